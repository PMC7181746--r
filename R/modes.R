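#' Classify a route into one of the three spread modes
#'
#' Over the five-layer network (T, P, I, C, LM; see [layer_ranks()]) every
#' route falls into exactly one mode: *inter-layer sequential* spread lands
#' in the next layer outward (T to P, P to I, I to C, C to LM), *inter-layer
#' skip* spread jumps past at least one layer (e.g. T to I, T to LM, P to
#' LM), and *intra-layer* spread stays within a layer (P to P, LM to LM).
#'
#' @param source_lesion,target_lesion Lesion IDs.
#' @param lesions Data.frame with `lesion_id`, `layer`.
#' @return `"sequential"`, `"skip"` or `"intra"`.
#' @examples
#' lesions <- data.frame(lesion_id = c("T", "P1", "LM1"),
#'                       layer = c("T", "P", "LM"))
#' classify_mode("T", "P1", lesions)   # sequential
#' classify_mode("T", "LM1", lesions)  # skip
#' @export
classify_mode <- function(source_lesion, target_lesion, lesions) {
  rs <- layer_rank(lesions$layer[match(source_lesion, lesions$lesion_id)])
  rt <- layer_rank(lesions$layer[match(target_lesion, lesions$lesion_id)])
  if (is.na(rs) || is.na(rt))
    stop("classify_mode: unknown lesion ", source_lesion, " or ", target_lesion)
  d <- rt - rs
  if (d < 0) stop("classify_mode: route ", source_lesion, " -> ",
                  target_lesion, " runs against the layer order")
  if (d == 0L) "intra" else if (d == 1L) "sequential" else "skip"
}

#' Round half up to one decimal
#'
#' Percentage rounding used throughout the reporting functions: one decimal
#' place, halves rounded up (so 38/61 prints as 62.3).
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  floor(x * f + 0.5 + 1e-9) / f
}

pct <- function(k, n) if (n == 0) 0 else round_half_up(100 * k / n)

#' Summarize a set of metastatic routes
#'
#' Counts and percentages of routes by origin (primary-, LNM- or
#' LM-initiated), by spread mode (sequential / skip / intra) and by seeding
#' class (monoclonal / multiclonal). Percentages are reported to one
#' decimal, halves up.
#'
#' @param routes Data.frame with columns `source_lesion`, `target_lesion`
#'   and optionally `mode` and `seeding_class` (missing `mode` is derived
#'   from the lesion layers). A `metastatic_map` is also accepted.
#' @param lesions Data.frame with `lesion_id`, `layer` (unused when `routes`
#'   is a `metastatic_map`).
#' @return A list of class `"route_summary"` with `n_routes`, `by_origin`,
#'   `by_mode`, `by_seeding` (each a data.frame of counts and percentages).
#' @export
summarize_routes <- function(routes, lesions = NULL) {
  if (inherits(routes, "metastatic_map")) {
    lesions <- routes$lesions
    routes <- routes$routes
  }
  n <- nrow(routes)
  breakdown <- function(values, levels) {
    counts <- as.integer(table(factor(values, levels = levels)))
    data.frame(category = levels, count = counts,
               percent = vapply(counts, pct, numeric(1), n = n),
               stringsAsFactors = FALSE)
  }
  if (n == 0) {
    empty <- function(levels) data.frame(category = levels,
                                         count = 0L, percent = 0,
                                         stringsAsFactors = FALSE)
    return(structure(list(n_routes = 0L,
                          by_origin = empty(c("primary", "LNM", "LM")),
                          by_mode = empty(c("sequential", "skip", "intra")),
                          by_seeding = empty(c("monoclonal", "multiclonal"))),
                     class = "route_summary"))
  }
  src_layer <- lesions$layer[match(routes$source_lesion, lesions$lesion_id)]
  if (anyNA(src_layer))
    stop("summarize_routes: route source(s) missing from the lesion table")
  origin <- ifelse(src_layer == "T", "primary",
                   ifelse(src_layer == "LM", "LM", "LNM"))
  if (is.null(routes$mode))
    routes$mode <- vapply(seq_len(n), function(i)
      classify_mode(routes$source_lesion[i], routes$target_lesion[i], lesions),
      character(1))
  out <- list(n_routes = n,
              by_origin = breakdown(origin, c("primary", "LNM", "LM")),
              by_mode = breakdown(routes$mode,
                                  c("sequential", "skip", "intra")))
  out$by_seeding <- if (is.null(routes$seeding_class)) NULL else
    breakdown(routes$seeding_class, c("monoclonal", "multiclonal"))
  structure(out, class = "route_summary")
}

#' @export
print.route_summary <- function(x, ...) {
  cat(sprintf("Route summary: %d routes\n", x$n_routes))
  show <- function(title, df) {
    if (is.null(df)) return()
    cat(" ", title, ": ",
        paste(sprintf("%s %d (%.1f%%)", df$category, df$count, df$percent),
              collapse = ", "), "\n", sep = "")
  }
  show("origin", x$by_origin)
  show("mode", x$by_mode)
  show("seeding", x$by_seeding)
  invisible(x)
}

#' Mutation sharing fractions across samples
#'
#' Partitions a patient's mutation universe by breadth of presence: shared
#' by all tumor samples, shared by two or more (but not all) samples, or
#' private to a single sample. Presence is binary — a mutation is present
#' in a sample when its CCF exceeds the absence threshold. Also reports the
#' fraction of mutations present both in the primary lesion and in at
#' least one metastasis.
#'
#' @param dataset A [patient_dataset()] with at least two samples.
#' @return A list with counts and one-decimal percentages:
#'   `n_mutations`, `shared_all`, `shared_some`, `private`,
#'   `primary_met_shared` (each a list `count`/`percent`).
#' @export
shared_mutation_fractions <- function(dataset) {
  stopifnot(inherits(dataset, "patient_dataset"))
  thr <- dataset$thresholds
  mut <- dataset$mutations
  samples <- sort(unique(dataset$regions$sample_id))
  if (length(samples) < 2L)
    stop("shared_mutation_fractions: sharing is undefined for a single sample")
  ids <- sort(unique(mut$mutation_id))
  pres <- matrix(FALSE, nrow = length(ids), ncol = length(samples),
                 dimnames = list(ids, samples))
  hit <- mut$ccf > thr$absent_ccf
  pres[cbind(match(mut$mutation_id, ids), match(mut$sample_id, samples))[hit, ,
       drop = FALSE]] <- TRUE
  breadth <- rowSums(pres)
  keep <- breadth > 0
  pres <- pres[keep, , drop = FALSE]
  breadth <- breadth[keep]
  n <- length(breadth)
  if (n == 0) stop("shared_mutation_fractions: no mutation present anywhere")
  n_all <- sum(breadth == ncol(pres))
  n_private <- sum(breadth == 1L)
  n_some <- n - n_all - n_private
  primary_lesion <- dataset$lesions$lesion_id[dataset$lesions$layer == "T"]
  primary_samples <- dataset$regions$sample_id[
    dataset$regions$lesion_id == primary_lesion]
  met_samples <- setdiff(samples, primary_samples)
  n_pm <- sum(rowSums(pres[, intersect(samples, primary_samples), drop = FALSE]) > 0 &
              rowSums(pres[, met_samples, drop = FALSE]) > 0)
  as_entry <- function(k) list(count = k, percent = pct(k, n))
  list(n_mutations = n,
       shared_all = as_entry(n_all),
       shared_some = as_entry(n_some),
       private = as_entry(n_private),
       primary_met_shared = as_entry(n_pm))
}
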