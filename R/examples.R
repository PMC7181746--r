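#' Build a patient dataset from a cluster-level CCF matrix
#'
#' Expands a transcribed cluster-by-lesion mean-CCF matrix into a
#' mutation-level dataset: each cluster contributes `n_mutations` member
#' mutations, every member carries the cluster's CCF in every region of a
#' lesion (so multi-region merging and cluster averaging reproduce the
#' matrix exactly). Useful for encoding published oval-plot summaries and
#' for building test instances.
#'
#' @param patient_id Patient identifier.
#' @param ccf Numeric matrix, clusters x lesions, with dimnames.
#' @param layers Named character vector: layer per lesion (names =
#'   lesion IDs, matching `colnames(ccf)`).
#' @param n_mutations Named integer vector of member counts per cluster.
#' @param n_regions Named integer vector of regions per lesion (default 1
#'   for every lesion).
#' @param depth Sequencing depth written into every call. Default 264.
#' @param thresholds Optional [threshold_config()].
#' @return A [patient_dataset()].
#' @export
dataset_from_ccf <- function(patient_id, ccf, layers, n_mutations,
                             n_regions = NULL, depth = 264,
                             thresholds = NULL) {
  stopifnot(is.matrix(ccf), !is.null(rownames(ccf)), !is.null(colnames(ccf)))
  lesion_ids <- colnames(ccf)
  if (!all(lesion_ids %in% names(layers)))
    stop("dataset_from_ccf: layers must name every lesion")
  if (!all(rownames(ccf) %in% names(n_mutations)))
    stop("dataset_from_ccf: n_mutations must name every cluster")
  if (is.null(n_regions))
    n_regions <- stats::setNames(rep(1L, length(lesion_ids)), lesion_ids)

  samples_of <- lapply(lesion_ids, function(l) {
    nr <- if (l %in% names(n_regions)) n_regions[[l]] else 1L
    if (nr == 1L) l else paste0(l, "_R", seq_len(nr))
  })
  names(samples_of) <- lesion_ids
  regions <- data.frame(
    sample_id = unlist(samples_of, use.names = FALSE),
    lesion_id = rep(lesion_ids, lengths(samples_of)),
    stringsAsFactors = FALSE)
  lesions <- data.frame(lesion_id = lesion_ids,
                        layer = unname(layers[lesion_ids]),
                        stringsAsFactors = FALSE)

  clusters <- rownames(ccf)
  mut_ids <- unlist(lapply(clusters, function(cl)
    sprintf("%s_m%02d", cl, seq_len(n_mutations[[cl]]))), use.names = FALSE)
  cluster_of <- rep(clusters, times = n_mutations[clusters])
  all_samples <- regions$sample_id
  lesion_of_sample <- stats::setNames(regions$lesion_id, regions$sample_id)
  mutations <- do.call(rbind, lapply(all_samples, function(s)
    data.frame(mutation_id = mut_ids, sample_id = s,
               ccf = unname(ccf[cluster_of, lesion_of_sample[[s]]]),
               depth = depth, cluster_id = cluster_of,
               stringsAsFactors = FALSE)))
  rownames(mutations) <- NULL
  patient_dataset(patient_id, mutations, lesions, regions, thresholds)
}

#' Synthetic reconstruction of the Patient_8 case study
#'
#' A worked example: a colorectal primary (two regions), seven paracolic
#' LNMs, two intermediate LNMs and one central LNM, with seven shared
#' mutation clusters (plus one leaf cluster private to P5). The CCF values
#' are a synthetic transcription — chosen to encode the narrative facts of
#' the published case: cluster 1 is the trunk/MRCA; cluster 2 is present
#' everywhere but subclonal in the primary (hence a branch, not a trunk);
#' I1 carries clusters 1-4 all clonal (monoclonal seeding by the "brown"
#' subclone) and I2 carries clusters 1-2 (monoclonal, "red"); P9 is seeded
#' multiclonally by clusters 2, 3 and 6; P2 and P5 by clusters 2-5; the
#' "purple" cluster 7 is shared exclusively by P6 (subclonal) and P7/P8
#' (clonal), so P7 and P8 are reseeded by P6 while P6 itself descends from
#' the primary.
#'
#' @return A [patient_dataset()].
#' @examples
#' res <- analyze_patient(example_patient8())
#' res$map
#' @export
example_patient8 <- function() {
  lesions <- c("T", "P1", "P2", "P5", "P6", "P7", "P8", "P9", "I1", "I2", "C1")
  ccf <- rbind(
    c1 = c(1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00, 1.00),
    c2 = c(0.80, 0.95, 0.95, 0.95, 0.95, 1.00, 1.00, 0.95, 1.00, 0.95, 0.95),
    c3 = c(0.50, 0.50, 0.60, 0.60, 0.35, 0.10, 0.10, 0.60, 0.95, 0.00, 0.40),
    c4 = c(0.30, 0.25, 0.30, 0.30, 0.00, 0.00, 0.00, 0.00, 0.90, 0.00, 0.00),
    c5 = c(0.15, 0.00, 0.20, 0.22, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00),
    c6 = c(0.10, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.30, 0.00, 0.00, 0.00),
    c7 = c(0.00, 0.00, 0.00, 0.00, 0.45, 0.90, 0.90, 0.00, 0.00, 0.00, 0.00),
    c8 = c(0.00, 0.00, 0.00, 0.15, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00))
  colnames(ccf) <- lesions
  layers <- stats::setNames(
    c("T", "P", "P", "P", "P", "P", "P", "P", "I", "I", "C"), lesions)
  n_mutations <- c(c1 = 30L, c2 = 20L, c3 = 15L, c4 = 12L, c5 = 8L,
                   c6 = 7L, c7 = 10L, c8 = 6L)
  dataset_from_ccf("Patient_8", ccf, layers, n_mutations,
                   n_regions = c("T" = 2L))
}

#' Synthetic reconstruction of the Patient_10 liver-metastasis case
#'
#' A worked example of liver-metastasis seeding: three LMs, all from
#' monoclonal seeding. LM3 shares a "brown" subclone (cluster 3) exclusively
#' with the primary, so it was seeded directly from the primary. LM1 and
#' LM2 share a "green" subclone (cluster 2) with the primary and a
#' "magenta" subclone (cluster 4) — clonal in both — found nowhere else:
#' one of them was seeded by the primary and reseeded the other, but their
#' identical clonal composition makes the direction unidentifiable. The
#' conventional resolution seeds LM2 from the primary and LM1 from LM2,
#' flagged as an ambiguity group. CCF values are synthetic transcriptions
#' encoding these narrative facts.
#'
#' @return A [patient_dataset()].
#' @examples
#' res <- analyze_patient(example_patient10())
#' res$map$ambiguity_groups
#' @export
example_patient10 <- function() {
  lesions <- c("T", "LM1", "LM2", "LM3")
  ccf <- rbind(
    c1 = c(1.00, 1.00, 1.00, 1.00),
    c2 = c(0.55, 1.00, 1.00, 0.00),
    c3 = c(0.40, 0.00, 0.00, 0.95),
    c4 = c(0.00, 0.95, 0.95, 0.00))
  colnames(ccf) <- lesions
  layers <- stats::setNames(c("T", "LM", "LM", "LM"), lesions)
  n_mutations <- c(c1 = 40L, c2 = 12L, c3 = 10L, c4 = 8L)
  dataset_from_ccf("Patient_10", ccf, layers, n_mutations,
                   n_regions = c("T" = 2L, LM1 = 2L, LM2 = 2L, LM3 = 2L))
}
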