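#' Run the full per-patient analysis
#'
#' Chains the pipeline stages: cluster-by-lesion mean CCFs (with
#' multi-region merging), cluster filtering, clonality calling, role
#' classification, clone-tree reconstruction, metastatic-map inference and
#' route summarization. Every filtering and inference decision is collected
#' in the returned `log`.
#'
#' @param dataset A [patient_dataset()].
#' @param thresholds A [threshold_config()]; defaults to the dataset's own.
#' @return A list of class `"metroutes_analysis"`: `matrix`, `status`,
#'   `roles`, `tree`, `ovals`, `map`, `summary`, `log`.
#' @examples
#' res <- analyze_patient(example_patient8())
#' res$summary
#' @export
analyze_patient <- function(dataset, thresholds = NULL) {
  stopifnot(inherits(dataset, "patient_dataset"))
  thresholds <- as_threshold_config(thresholds %||% dataset$thresholds)
  log <- mr_new_log()
  mat <- cluster_lesion_ccf(dataset)
  mat <- filter_clusters(mat, thresholds, log = log)
  status <- call_clonality(mat, thresholds)
  unobserved <- rownames(status)[rowSums(status != "absent") == 0]
  if (length(unobserved)) {
    for (cl in unobserved)
      mr_log(log, "cluster %s dropped: absent in every lesion after clonality calling",
             cl)
    keep <- setdiff(rownames(status), unobserved)
    status <- status[keep, , drop = FALSE]
    mat <- structure(list(ccf = mat$ccf[keep, , drop = FALSE],
                          n_mutations = mat$n_mutations[keep],
                          chromosomes = if (is.null(mat$chromosomes)) NULL
                                        else mat$chromosomes[keep]),
                     class = "cluster_ccf")
  }
  roles <- classify_cluster_roles(status)
  tree <- build_clone_tree(mat, status, roles,
                           epsilon = thresholds$ccf_epsilon, log = log)
  ovals <- nested_ovals(tree, status, mat, strict = FALSE)
  for (les in names(ovals))
    for (v in attr(ovals[[les]], "violations"))
      mr_log(log, "nesting warning: %s", v)
  map <- infer_metastatic_map(dataset, tree, status, log = log)
  summ <- summarize_routes(map)
  structure(list(matrix = mat, status = status, roles = roles, tree = tree,
                 ovals = ovals, map = map, summary = summ,
                 thresholds = thresholds, log = mr_log_lines(log)),
            class = "metroutes_analysis")
}

#' @export
print.metroutes_analysis <- function(x, ...) {
  cat("== metroutes analysis ==\n")
  print(x$tree)
  print(x$map)
  print(x$summary)
  invisible(x)
}

#' Write all pipeline outputs for one patient
#'
#' Writes `routes.tsv`, `tree.newick`, `map.dot`, `summary.json` and
#' `run.log` into a directory.
#'
#' @param analysis A `"metroutes_analysis"` from [analyze_patient()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "metroutes_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_route_table(analysis$map, file.path(dir, "routes.tsv"))
  write_tree_newick(analysis$tree, file.path(dir, "tree.newick"))
  write_map_dot(analysis$map, file.path(dir, "map.dot"))
  s <- analysis$summary
  jsonlite::write_json(
    list(n_routes = s$n_routes, by_origin = s$by_origin,
         by_mode = s$by_mode, by_seeding = s$by_seeding,
         ambiguity_groups = analysis$map$ambiguity_groups),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  writeLines(analysis$log, file.path(dir, "run.log"))
  invisible(dir)
}
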