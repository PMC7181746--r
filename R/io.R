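#' Read a per-mutation CCF table
#'
#' Reads a tab-separated mutation table of the kind produced by PyClone-style
#' post-processing: one row per mutation per sequenced sample, with the CCF
#' estimate, per-sample sequencing depth and the mutation-cluster assignment.
#' CCF values are read verbatim (estimates above 1 are permitted on input;
#' capping happens only inside [merge_ccf()]).
#'
#' Required columns: `mutation_id`, `sample_id`, `ccf`, `depth`,
#' `cluster_id`. Optional columns `ref_count`, `alt_count`, `major_cn`,
#' `minor_cn`, `purity` are validated if present; any further columns are
#' carried through untouched.
#'
#' @param path Path to a TSV file with a header row.
#' @return A data.frame of validated mutation calls.
#' @seealso [read_lesion_table()], [patient_dataset()]
#' @export
read_mutation_table <- function(path) {
  if (!file.exists(path)) stop("mutation table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  required <- c("mutation_id", "sample_id", "ccf", "depth", "cluster_id")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("mutation table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  df$ccf <- parse_numeric_column(df$ccf, "ccf")
  df$depth <- parse_numeric_column(df$depth, "depth")
  for (col in intersect(c("ref_count", "alt_count", "purity"), names(df)))
    df[[col]] <- parse_numeric_column(df[[col]], col)
  validate_mutation_calls(df)
  df
}

parse_numeric_column <- function(x, name) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out))
  if (length(bad))
    stop(sprintf("non-numeric value %s in column '%s' at data row %d",
                 dQuote(x[bad[1]]), name, bad[1]))
  out
}

validate_mutation_calls <- function(df) {
  if (any(df$depth < 1))
    stop("mutation table: depth must be >= 1 (first offending row ",
         which(df$depth < 1)[1], ")")
  if (any(df$ccf < 0))
    stop("mutation table: ccf must be >= 0 (first offending row ",
         which(df$ccf < 0)[1], ")")
  if (all(c("ref_count", "alt_count") %in% names(df))) {
    if (any(df$alt_count < 0) || any(df$ref_count < 0))
      stop("mutation table: read counts must be non-negative")
  }
  dup <- duplicated(df[c("mutation_id", "sample_id")])
  if (any(dup))
    stop("mutation table: mutation ", df$mutation_id[which(dup)[1]],
         " appears more than once in sample ", df$sample_id[which(dup)[1]])
  # a mutation must keep one cluster assignment across samples
  cl <- tapply(df$cluster_id, df$mutation_id,
               function(v) length(unique(v)))
  if (any(cl > 1))
    stop("mutation table: mutation ", names(cl)[which(cl > 1)[1]],
         " is assigned to more than one cluster across samples")
  invisible(df)
}

#' Read a lesion metadata table
#'
#' Reads a tab-separated table mapping sequenced samples (regions) to
#' lesions, one row per region, with columns `lesion_id`, `layer` and
#' `sample_id`. Layers must be in `T`, `P`, `I`, `C`, `LM` (see
#' [layer_ranks()]); exactly one lesion per patient carries layer `T`, and a
#' sample may belong to only one lesion.
#'
#' @param path Path to a TSV file with a header row.
#' @return A list with `lesions` (data.frame `lesion_id`, `layer`) and
#'   `regions` (data.frame `sample_id`, `lesion_id`).
#' @export
read_lesion_table <- function(path) {
  if (!file.exists(path)) stop("lesion table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  required <- c("lesion_id", "layer", "sample_id")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("lesion table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  build_lesions(df)
}

build_lesions <- function(df) {
  layer_rank(df$layer)  # validates the enum
  if (anyDuplicated(df$sample_id))
    stop("lesion table: sample ", df$sample_id[duplicated(df$sample_id)][1],
         " is assigned to more than one lesion/region row")
  per_lesion <- unique(df[c("lesion_id", "layer")])
  if (anyDuplicated(per_lesion$lesion_id))
    stop("lesion table: lesion ",
         per_lesion$lesion_id[duplicated(per_lesion$lesion_id)][1],
         " is given more than one layer")
  n_primary <- sum(per_lesion$layer == "T")
  if (n_primary != 1L)
    stop("lesion table must define exactly one primary (layer T) lesion, found ",
         n_primary)
  ord <- order(layer_rank(per_lesion$layer), per_lesion$lesion_id)
  lesions <- per_lesion[ord, , drop = FALSE]
  rownames(lesions) <- NULL
  regions <- df[c("sample_id", "lesion_id")]
  rownames(regions) <- NULL
  list(lesions = lesions, regions = regions)
}

#' Assemble a per-patient dataset
#'
#' Bundles the mutation calls and lesion metadata of one patient and checks
#' their cross-references: every sequenced sample referenced by the mutation
#' table must map to exactly one lesion.
#'
#' @param patient_id Patient identifier string.
#' @param mutations Data.frame as returned by [read_mutation_table()].
#' @param lesions,regions Data.frames as returned by [read_lesion_table()]
#'   (`$lesions` and `$regions`).
#' @param thresholds A [threshold_config()] (defaults used when `NULL`).
#' @return A list of class `"patient_dataset"`.
#' @export
patient_dataset <- function(patient_id, mutations, lesions, regions,
                            thresholds = NULL) {
  validate_mutation_calls(mutations)
  unknown <- setdiff(unique(mutations$sample_id), regions$sample_id)
  if (length(unknown))
    stop("mutation table references sample(s) not assigned to any lesion: ",
         paste(unknown, collapse = ", "))
  unknown_lesion <- setdiff(regions$lesion_id, lesions$lesion_id)
  if (length(unknown_lesion))
    stop("region map references unknown lesion(s): ",
         paste(unknown_lesion, collapse = ", "))
  structure(list(patient_id = patient_id, mutations = mutations,
                 lesions = lesions, regions = regions,
                 thresholds = as_threshold_config(thresholds)),
            class = "patient_dataset")
}

#' @export
print.patient_dataset <- function(x, ...) {
  cat(sprintf("Patient dataset '%s': %d lesions, %d samples, %d mutations (%d clusters)\n",
              x$patient_id, nrow(x$lesions), length(unique(x$mutations$sample_id)),
              length(unique(x$mutations$mutation_id)),
              length(unique(x$mutations$cluster_id))))
  lay <- table(factor(x$lesions$layer, levels = names(layer_ranks())))
  cat("  layers:", paste(sprintf("%s=%d", names(lay), lay), collapse = " "), "\n")
  invisible(x)
}

#' Write the mutation and lesion tables of a dataset
#'
#' Writes the two TSV inputs back out (round-trip safe for programmatic
#' generation and sharing of synthetic datasets).
#'
#' @param dataset A [patient_dataset()].
#' @param mutations_path,lesions_path Output TSV paths.
#' @return Invisibly, the dataset.
#' @export
write_patient_tables <- function(dataset, mutations_path, lesions_path) {
  stopifnot(inherits(dataset, "patient_dataset"))
  utils::write.table(dataset$mutations, mutations_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  lt <- merge(dataset$regions, dataset$lesions, by = "lesion_id", sort = FALSE)
  lt <- lt[order(layer_rank(lt$layer), lt$lesion_id, lt$sample_id),
           c("lesion_id", "layer", "sample_id")]
  utils::write.table(lt, lesions_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dataset)
}

#' Write an inferred route table
#'
#' One row per seeding event with the source and target lesion, the seeding
#' clone set (semicolon-joined), its size, the monoclonal/multiclonal call,
#' the spread mode, and the color cluster (the most-derived seeding clone,
#' which the map drawings are colored by). An empty map yields a header-only
#' file.
#'
#' @param map A `metastatic_map` from [infer_metastatic_map()].
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_route_table <- function(map, path) {
  stopifnot(inherits(map, "metastatic_map"))
  df <- map$routes
  out <- data.frame(patient_id = rep(map$patient_id, nrow(df)),
                    source_lesion = df$source_lesion,
                    target_lesion = df$target_lesion,
                    seeding_clones = df$seeding_clones,
                    n_seeding_clones = df$n_seeding_clones,
                    seeding_class = df$seeding_class,
                    mode = df$mode,
                    color_cluster = df$color_cluster,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a clone tree in Newick format
#'
#' Labels are cluster IDs (internal nodes included); branch lengths are the
#' number of member substitutions of each cluster, mirroring trees whose
#' branch lengths are drawn proportional to mutation counts.
#'
#' @param tree A `clone_tree` from [build_clone_tree()].
#' @param path Output file path, or `NULL` to return the string.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_tree_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "clone_tree"))
  children <- split(names(tree$parent)[!is.na(tree$parent)],
                    tree$parent[!is.na(tree$parent)])
  emit <- function(node) {
    kids <- sort(children[[node]] %||% character())
    lab <- node
    if (!is.null(tree$n_mutations) && node %in% names(tree$n_mutations))
      lab <- sprintf("%s:%d", node, as.integer(tree$n_mutations[[node]]))
    if (!length(kids)) return(lab)
    paste0("(", paste(vapply(kids, emit, character(1)), collapse = ","), ")", lab)
  }
  nwk <- paste0(emit(tree$root), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Write a metastatic map in DOT format
#'
#' Lesions become graph nodes annotated with their layer; seeding routes
#' become directed edges labeled (and colorable) by their color cluster.
#'
#' @param map A `metastatic_map` from [infer_metastatic_map()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_map_dot <- function(map, path) {
  stopifnot(inherits(map, "metastatic_map"))
  lesions <- map$lesions
  lines <- c(sprintf("digraph \"%s\" {", map$patient_id),
             "  rankdir=LR;")
  for (i in seq_len(nrow(lesions)))
    lines <- c(lines, sprintf("  \"%s\" [label=\"%s\\n(%s)\"];",
                              lesions$lesion_id[i], lesions$lesion_id[i],
                              lesions$layer[i]))
  df <- map$routes
  for (i in seq_len(nrow(df)))
    lines <- c(lines,
               sprintf("  \"%s\" -> \"%s\" [label=\"%s|%s\"];",
                       df$source_lesion[i], df$target_lesion[i],
                       df$color_cluster[i], df$mode[i]))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
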