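#' Convert read counts to a cancer cell fraction
#'
#' Standard purity/copy-number conversion of a variant allele fraction into
#' the fraction of cancer cells carrying the variant:
#' `CCF = VAF * (purity * total_cn + (1 - purity) * 2) / (purity * multiplicity)`.
#' The result is clipped to `[0, 1.5]`; values above 1 are retained at this
#' stage (they carry information about copy-number/multiplicity misfits) and
#' are capped only by the downstream depth-weighted merge.
#'
#' @param alt_count,ref_count Variant and reference read counts (vectors
#'   allowed; `alt + ref` must be >= 1).
#' @param purity Tumor purity in (0, 1].
#' @param total_cn Total copy number at the locus (>= 1). Default 2.
#' @param multiplicity Number of mutated copies (>= 1). Default 1.
#' @return CCF estimate(s) in `[0, 1.5]`.
#' @examples
#' ccf_from_counts(50, 50, purity = 1)            # diploid clonal het -> 1
#' ccf_from_counts(30, 70, purity = 0.6)          # 0.3 * 2 / 0.6 -> 1
#' @export
ccf_from_counts <- function(alt_count, ref_count, purity, total_cn = 2,
                            multiplicity = 1) {
  n <- alt_count + ref_count
  if (any(n < 1)) stop("ccf_from_counts: zero total reads")
  if (any(purity <= 0) || any(purity > 1))
    stop("ccf_from_counts: purity must be in (0, 1]")
  if (any(total_cn < 1) || any(multiplicity < 1))
    stop("ccf_from_counts: total_cn and multiplicity must be >= 1")
  vaf <- alt_count / n
  ccf <- vaf * (purity * total_cn + (1 - purity) * 2) / (purity * multiplicity)
  pmin(pmax(ccf, 0), 1.5)
}

#' Depth-weighted merge of per-region CCFs
#'
#' Multiple regions sequenced from the same lesion collectively reflect its
#' clonal composition and are analyzed as a single sample. The merged CCF of
#' a mutation is the sequencing-depth-weighted mean of its per-region CCF
#' estimates, capped at 1:
#' \deqn{\mathrm{CCF} = \min\!\left(1,\; \frac{\sum_i \mathrm{CCF}_i d_i}{\sum_i d_i}\right)}
#'
#' @param ccfs Numeric vector of per-region CCF estimates (values > 1
#'   permitted; the merged value is capped).
#' @param depths Numeric vector of per-region sequencing depths (>= 1), same
#'   length as `ccfs`.
#' @return Merged CCF in `[0, 1]`.
#' @examples
#' merge_ccf(c(0.8, 0.4), c(100, 300))  # (80 + 120) / 400 = 0.5
#' merge_ccf(c(1.2, 1.0), c(50, 50))    # capped at 1
#' @export
merge_ccf <- function(ccfs, depths) {
  if (length(ccfs) == 0L || length(ccfs) != length(depths))
    stop("merge_ccf: ccfs and depths must be non-empty and of equal length")
  if (any(depths < 1)) stop("merge_ccf: depths must be >= 1")
  if (any(ccfs < 0)) stop("merge_ccf: CCFs must be >= 0")
  min(1, sum(ccfs * depths) / sum(depths))
}

#' Per-cluster, per-lesion mean CCF matrix
#'
#' Collapses the per-mutation, per-sample CCF calls of a patient into a
#' cluster-by-lesion matrix. For lesions sequenced in several regions, each
#' mutation's CCF is first merged across that lesion's regions with
#' [merge_ccf()]; a cluster's value per lesion is then the arithmetic mean
#' over its member mutations. Mutations without a call in a covered sample
#' are imputed as CCF 0 at that sample's median depth (absence of a call in
#' a covered region is evidence of absence).
#'
#' @param dataset A [patient_dataset()].
#' @return A list of class `"cluster_ccf"` with elements `ccf` (numeric
#'   matrix, clusters x lesions, values in `[0, 1]`), `n_mutations` (named
#'   integer vector) and `chromosomes` (named list of chromosome labels when
#'   mutation IDs look like `chrom:...`, else `NULL`).
#' @export
cluster_lesion_ccf <- function(dataset) {
  stopifnot(inherits(dataset, "patient_dataset"))
  mut <- dataset$mutations
  samples <- sort(unique(dataset$regions$sample_id))
  mut_ids <- sort(unique(mut$mutation_id))
  if (!length(mut_ids)) stop("cluster_lesion_ccf: no mutations in dataset")

  ccf_ms <- matrix(0, nrow = length(mut_ids), ncol = length(samples),
                   dimnames = list(mut_ids, samples))
  med_depth <- tapply(mut$depth, mut$sample_id, stats::median)
  depth_ms <- matrix(rep(ifelse(is.na(med_depth[samples]), 100, med_depth[samples]),
                         each = length(mut_ids)),
                     nrow = length(mut_ids), ncol = length(samples),
                     dimnames = list(mut_ids, samples))
  idx <- cbind(match(mut$mutation_id, mut_ids), match(mut$sample_id, samples))
  ccf_ms[idx] <- mut$ccf
  depth_ms[idx] <- mut$depth

  cluster_of <- tapply(mut$cluster_id, mut$mutation_id, function(v) v[1])
  cluster_of <- cluster_of[mut_ids]
  clusters <- sort(unique(as.character(cluster_of)))

  lesion_ids <- dataset$lesions$lesion_id
  merged <- matrix(0, nrow = length(mut_ids), ncol = length(lesion_ids),
                   dimnames = list(mut_ids, lesion_ids))
  for (les in lesion_ids) {
    cols <- dataset$regions$sample_id[dataset$regions$lesion_id == les]
    cols <- intersect(samples, cols)
    if (!length(cols))
      stop("lesion ", les, " has no sequenced regions")
    if (length(cols) == 1L) {
      merged[, les] <- pmin(1, ccf_ms[, cols])
    } else {
      merged[, les] <- vapply(mut_ids, function(m)
        merge_ccf(ccf_ms[m, cols], depth_ms[m, cols]), numeric(1))
    }
  }

  ccf <- matrix(0, nrow = length(clusters), ncol = length(lesion_ids),
                dimnames = list(clusters, lesion_ids))
  n_mutations <- integer(length(clusters))
  names(n_mutations) <- clusters
  for (cl in clusters) {
    members <- mut_ids[cluster_of == cl]
    n_mutations[cl] <- length(members)
    ccf[cl, ] <- colMeans(merged[members, , drop = FALSE])
  }

  chroms <- NULL
  if (all(grepl(":", mut_ids, fixed = TRUE))) {
    chrom_of <- sub(":.*$", "", mut_ids)
    chroms <- lapply(clusters, function(cl)
      unique(chrom_of[cluster_of == cl]))
    names(chroms) <- clusters
  }

  structure(list(ccf = ccf, n_mutations = n_mutations, chromosomes = chroms),
            class = "cluster_ccf")
}

#' Build a cluster-by-lesion matrix directly from values
#'
#' Convenience constructor for a `"cluster_ccf"` object when mean CCFs are
#' already available (e.g. transcribed summaries or tests).
#'
#' @param ccf Numeric matrix (clusters x lesions) with dimnames.
#' @param n_mutations Named integer vector of member-mutation counts
#'   (defaults to the retention threshold so nothing is filtered).
#' @param chromosomes Optional named list of chromosome label sets.
#' @return A `"cluster_ccf"` object.
#' @export
cluster_ccf_matrix <- function(ccf, n_mutations = NULL, chromosomes = NULL) {
  stopifnot(is.matrix(ccf), !is.null(rownames(ccf)), !is.null(colnames(ccf)))
  if (any(ccf < 0) || any(ccf > 1))
    stop("cluster_ccf_matrix: mean CCFs must lie in [0, 1]")
  if (is.null(n_mutations)) {
    n_mutations <- rep(5L, nrow(ccf))
    names(n_mutations) <- rownames(ccf)
  }
  if (!all(rownames(ccf) %in% names(n_mutations)))
    stop("cluster_ccf_matrix: n_mutations must name every cluster")
  structure(list(ccf = ccf, n_mutations = n_mutations[rownames(ccf)],
                 chromosomes = chromosomes),
            class = "cluster_ccf")
}

#' @export
print.cluster_ccf <- function(x, ...) {
  cat(sprintf("Cluster CCF matrix: %d clusters x %d lesions\n",
              nrow(x$ccf), ncol(x$ccf)))
  print(round(x$ccf, 3))
  invisible(x)
}

#' Call per-cluster, per-lesion clonality status
#'
#' A cluster is `clonal` in a lesion when its mean CCF strictly exceeds the
#' clonal threshold, `absent` when the mean CCF is at or below the absence
#' threshold, and `subclonal` otherwise. Boundary behavior follows the
#' inequalities verbatim: exactly 0.85 is subclonal, exactly 0.05 is absent
#' (at the default thresholds).
#'
#' @param matrix A `"cluster_ccf"` object.
#' @param thresholds A [threshold_config()].
#' @return Character matrix (same dimnames) over
#'   `{"clonal", "subclonal", "absent"}`.
#' @export
call_clonality <- function(matrix, thresholds = threshold_config()) {
  stopifnot(inherits(matrix, "cluster_ccf"))
  thresholds <- as_threshold_config(thresholds)
  m <- matrix$ccf
  status <- ifelse(m > thresholds$clonal_ccf, "clonal",
                   ifelse(m <= thresholds$absent_ccf, "absent", "subclonal"))
  dimnames(status) <- dimnames(m)
  status
}

#' Drop unreliable mutation clusters
#'
#' Clusters with fewer member mutations than the retention threshold are
#' potential false-positive calls and are removed; when enabled (and
#' chromosome annotations are available), clusters whose mutations are
#' confined to fewer than `min_chromosomes` chromosomes are removed too.
#' Retained values are untouched (pure selection).
#'
#' @param matrix A `"cluster_ccf"` object.
#' @param thresholds A [threshold_config()].
#' @param log Optional internal log buffer.
#' @return The filtered `"cluster_ccf"` object.
#' @export
filter_clusters <- function(matrix, thresholds = threshold_config(),
                            log = NULL) {
  stopifnot(inherits(matrix, "cluster_ccf"))
  thresholds <- as_threshold_config(thresholds)
  keep <- matrix$n_mutations >= thresholds$min_cluster_size
  for (cl in names(keep)[!keep])
    mr_log(log, "cluster %s dropped: %d mutations < min_cluster_size %d",
           cl, matrix$n_mutations[[cl]], thresholds$min_cluster_size)
  if (!is.null(thresholds$min_chromosomes) && !is.null(matrix$chromosomes)) {
    nchrom <- vapply(matrix$chromosomes[names(keep)], length, integer(1))
    chrom_ok <- nchrom >= thresholds$min_chromosomes
    for (cl in names(keep)[keep & !chrom_ok])
      mr_log(log, "cluster %s dropped: spans %d chromosomes < min_chromosomes %d",
             cl, nchrom[[cl]], thresholds$min_chromosomes)
    keep <- keep & chrom_ok
  }
  if (!any(keep))
    stop("filter_clusters: all clusters were dropped; nothing to analyze")
  kept <- names(keep)[keep]
  structure(list(ccf = matrix$ccf[kept, , drop = FALSE],
                 n_mutations = matrix$n_mutations[kept],
                 chromosomes = if (is.null(matrix$chromosomes)) NULL
                               else matrix$chromosomes[kept]),
            class = "cluster_ccf")
}
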