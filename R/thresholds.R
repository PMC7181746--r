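#' Analysis thresholds
#'
#' Bundles the cutoffs used throughout the pipeline. Defaults follow common
#' practice for PyClone-style CCF post-processing of deep exome data: a
#' mutation cluster is *clonal* in a lesion when its mean CCF exceeds
#' `clonal_ccf` (strict `>`), *absent* when the mean CCF is at or below
#' `absent_ccf` (`<=`), and *subclonal* otherwise. Clusters with fewer than
#' `min_cluster_size` member mutations are treated as potential false
#' positives and dropped; optionally clusters confined to fewer than
#' `min_chromosomes` chromosomes can be dropped too (disabled by default, as
#' there is no principled universal cutoff). `ccf_epsilon` is the tolerance
#' applied to every CCF comparison during subclonal-structure reconstruction.
#'
#' @param clonal_ccf CCF above which a cluster is called clonal. Default 0.85.
#' @param absent_ccf CCF at or below which a cluster is called absent.
#'   Default 0.05.
#' @param min_cluster_size Minimum number of member mutations for a cluster
#'   to be retained. Default 5.
#' @param ccf_epsilon Tolerance for CCF comparisons in the pigeonhole rules.
#'   Default 0.05 (same scale as the absence threshold).
#' @param min_chromosomes Minimum number of distinct chromosomes a cluster's
#'   mutations must span, or `NULL` (default) to disable the filter.
#' @return A list of class `"threshold_config"`.
#' @examples
#' threshold_config()
#' threshold_config(clonal_ccf = 0.9)
#' @export
threshold_config <- function(clonal_ccf = 0.85, absent_ccf = 0.05,
                             min_cluster_size = 5L, ccf_epsilon = 0.05,
                             min_chromosomes = NULL) {
  stopifnot(is.numeric(clonal_ccf), length(clonal_ccf) == 1L,
            is.numeric(absent_ccf), length(absent_ccf) == 1L,
            is.numeric(ccf_epsilon), length(ccf_epsilon) == 1L)
  if (!(absent_ccf >= 0 && absent_ccf < clonal_ccf && clonal_ccf <= 1))
    stop("thresholds must satisfy 0 <= absent_ccf < clonal_ccf <= 1")
  if (ccf_epsilon < 0) stop("ccf_epsilon must be >= 0")
  min_cluster_size <- as.integer(min_cluster_size)
  if (min_cluster_size < 1L) stop("min_cluster_size must be >= 1")
  if (!is.null(min_chromosomes)) {
    min_chromosomes <- as.integer(min_chromosomes)
    if (min_chromosomes < 1L) stop("min_chromosomes must be >= 1 or NULL")
  }
  structure(list(clonal_ccf = clonal_ccf, absent_ccf = absent_ccf,
                 min_cluster_size = min_cluster_size,
                 ccf_epsilon = ccf_epsilon,
                 min_chromosomes = min_chromosomes),
            class = "threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("Threshold configuration:\n")
  cat(sprintf("  clonal:   mean CCF > %.2f\n", x$clonal_ccf))
  cat(sprintf("  absent:   mean CCF <= %.2f\n", x$absent_ccf))
  cat(sprintf("  cluster filter: < %d mutations dropped\n", x$min_cluster_size))
  cat(sprintf("  comparison epsilon: %.3f\n", x$ccf_epsilon))
  cat(sprintf("  chromosome filter: %s\n",
              if (is.null(x$min_chromosomes)) "disabled"
              else sprintf("< %d chromosomes dropped", x$min_chromosomes)))
  invisible(x)
}

as_threshold_config <- function(x) {
  if (is.null(x)) return(threshold_config())
  if (inherits(x, "threshold_config")) return(x)
  do.call(threshold_config, x)
}
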