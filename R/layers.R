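#' Anatomic layers of the metastatic network
#'
#' The lesion network is dissected into five layers ordered by lymphatic
#' drainage from the primary tumor outward: `T` (primary tumor), `P`
#' (paracolic lymph node metastases), `I` (intermediate LNMs), `C` (central
#' LNMs) and `LM` (liver metastases). Lymph flow is unidirectional, so a
#' lymphatic lesion can only be seeded from the same or a more proximal
#' layer; liver metastases can be seeded from any layer but never seed back
#' into the lymphatic network.
#'
#' @return Named integer vector of layer ranks (`T` = 0 ... `LM` = 4).
#' @examples
#' layer_ranks()
#' @export
layer_ranks <- function() {
  c("T" = 0L, "P" = 1L, "I" = 2L, "C" = 3L, "LM" = 4L)
}

layer_rank <- function(layer) {
  rk <- layer_ranks()
  bad <- setdiff(unique(layer), names(rk))
  if (length(bad))
    stop("unknown layer label(s): ", paste(bad, collapse = ", "),
         " (expected T, P, I, C or LM)")
  unname(rk[layer])
}

# Is a route from layer `from` into layer `to` compatible with the
# unidirectional-lymph assumption?  LM targets accept any source; LM sources
# may only seed other LMs; lymphatic targets require rank(from) <= rank(to).
layer_route_ok <- function(from, to) {
  if (to == "LM") return(TRUE)
  if (from == "LM") return(FALSE)
  layer_rank(from) <= layer_rank(to)
}
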