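#' Classify mutation clusters as trunk, branch or leaf
#'
#' The unique cluster clonal in every lesion is the trunk; it corresponds to
#' the most recent clone ancestor (MRCA) of the patient's tumor. Non-trunk
#' clusters present (status not absent) in two or more lesions are branch
#' clusters; clusters present in exactly one lesion are leaf clusters. A
#' cluster present in all lesions but subclonal somewhere is a branch, not a
#' trunk.
#'
#' @param status Clonality matrix from [call_clonality()].
#' @return Data.frame with columns `cluster_id`, `role`.
#' @export
classify_cluster_roles <- function(status) {
  stopifnot(is.matrix(status))
  present <- status != "absent"
  n_present <- rowSums(present)
  if (any(n_present == 0))
    stop("cluster(s) absent in every lesion: ",
         paste(rownames(status)[n_present == 0], collapse = ", "))
  trunk_candidates <- rownames(status)[rowSums(status == "clonal") == ncol(status)]
  if (length(trunk_candidates) == 0L)
    stop("no trunk cluster: no cluster is clonal in all lesions (no MRCA)")
  if (length(trunk_candidates) > 1L)
    stop("ambiguous MRCA: clusters ",
         paste(trunk_candidates, collapse = ", "),
         " are all clonal in every lesion")
  role <- ifelse(rownames(status) == trunk_candidates, "trunk",
                 ifelse(n_present == 1L, "leaf", "branch"))
  data.frame(cluster_id = rownames(status), role = role,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pairwise subclone relationship from CCF profiles
#'
#' Applies the pigeonhole rules to two clusters' per-lesion CCF profiles:
#' they are *branching* (sister lineages) when their relative CCFs are
#' reversed between lesions beyond tolerance; they are *linear* (nested)
#' when one dominates the other in every lesion and either dominates
#' strictly somewhere or their CCFs sum above 1 somewhere (the two lineages
#' could not then be disjoint within one tumor). When a reversal and the
#' sum condition both fire, branching wins — a genuine reversal is direct
#' evidence of sister lineages. If neither rule fires the pair is
#' `undetermined` and is resolved during tree construction (defaulting to
#' branching under a common parent unless the sum rule forbids it).
#'
#' On an exact tie (identical profiles with sums above 1) the orientation is
#' not decidable from the values; the first argument is reported as parent.
#'
#' @param ccf_a,ccf_b Numeric per-lesion CCF vectors over the same lesions.
#' @param epsilon Comparison tolerance.
#' @return One of `"linear_a_over_b"`, `"linear_b_over_a"`, `"branching"`,
#'   `"undetermined"`.
#' @export
pairwise_relation <- function(ccf_a, ccf_b, epsilon = 0.05) {
  if (length(ccf_a) != length(ccf_b) || length(ccf_a) == 0L)
    stop("pairwise_relation: profiles must be non-empty and of equal length")
  rev_ab <- any(ccf_a > ccf_b + epsilon)  # a strictly above b somewhere
  rev_ba <- any(ccf_b > ccf_a + epsilon)
  if (rev_ab && rev_ba) return("branching")
  sum_high <- any(ccf_a + ccf_b > 1 + epsilon)
  if (rev_ab) return("linear_a_over_b")
  if (rev_ba) return("linear_b_over_a")
  if (sum_high) {
    ma <- mean(ccf_a); mb <- mean(ccf_b)
    if (mb > ma) return("linear_b_over_a")
    return("linear_a_over_b")
  }
  "undetermined"
}

# --- internal tree helpers -------------------------------------------------

tree_children <- function(parent) {
  split(names(parent)[!is.na(parent)], parent[!is.na(parent)])
}

#' Node depths of a clone tree
#'
#' @param tree A `clone_tree`.
#' @return Named integer vector of depths (root = 0).
#' @export
tree_depths <- function(tree) {
  parent <- tree$parent
  depths <- integer(length(parent))
  names(depths) <- names(parent)
  for (node in names(parent)) {
    d <- 0L; p <- parent[[node]]
    while (!is.na(p)) { d <- d + 1L; p <- parent[[p]] }
    depths[[node]] <- d
  }
  depths
}

tree_ancestors <- function(parent, node) {
  out <- character()
  p <- parent[[node]]
  while (!is.na(p)) { out <- c(out, p); p <- parent[[p]] }
  out
}

tree_descendants <- function(parent, node) {
  kids <- tree_children(parent)
  out <- character()
  frontier <- node
  while (length(frontier)) {
    nxt <- unlist(kids[frontier], use.names = FALSE)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

# Pigeonhole validity of a complete parent assignment over the given nodes.
# Hard constraints (all per-lesion, with tolerance epsilon):
#   - nesting: a child's CCF never exceeds its parent's;
#   - a pair with a CCF reversal between lesions (branching evidence) must
#     not be nested — nested clones cannot reverse;
#   - a pair whose CCFs sum above 1 in some lesion must be nested — two
#     disjoint lineages cannot jointly exceed the whole tumor;
#   - two non-nested lineages can never jointly exceed a common ancestor's
#     CCF.
# One-sided dominance without a reversal is treated as evidence, not a
# constraint: it steers the parent preference but does not reject trees.
tree_is_valid <- function(parent, nodes, ccf, rel, epsilon) {
  anc <- lapply(nodes, function(n) tree_ancestors(parent, n))
  names(anc) <- nodes
  for (n in nodes) {
    p <- parent[[n]]
    if (is.na(p)) next
    if (any(ccf[n, ] > ccf[p, ] + epsilon)) return(FALSE)
  }
  n_nodes <- length(nodes)
  for (i in seq_len(n_nodes)) {
    for (j in seq_len(n_nodes)) {
      if (j <= i) next
      a <- nodes[i]; b <- nodes[j]
      r <- rel[[paste(a, b, sep = "|")]]
      nested <- a %in% anc[[b]] || b %in% anc[[a]]
      if (r == "branching" && nested) return(FALSE)
      # sum-based rules compare two estimated quantities against a third,
      # so their tolerance is doubled relative to single comparisons
      sum_high <- any(ccf[a, ] + ccf[b, ] > 1 + 2 * epsilon)
      if (sum_high && !nested) return(FALSE)
      if (!nested) {
        common <- intersect(c(a, anc[[a]]), c(b, anc[[b]]))
        for (g in common)
          if (any(ccf[a, ] + ccf[b, ] > ccf[g, ] + 2 * epsilon)) return(FALSE)
      }
    }
  }
  TRUE
}

#' Reconstruct the clone tree from CCF constraints
#'
#' Searches for the rooted tree of mutation clusters (root = trunk/MRCA)
#' consistent with the pigeonhole rules: linear pairs must be nested,
#' branching pairs must be sisters, the CCF of a cluster never exceeds its
#' parent's (within tolerance) in any lesion, and two sister lineages can
#' never jointly exceed a common ancestor's CCF in any lesion. The search is
#' exhaustive over parent assignments (with constraint pruning), so whenever
#' the constraints single out one tree, that tree is returned. When several
#' trees remain consistent, the deterministic preference picks, node by
#' node, the most derived feasible parent: smallest maximum CCF across
#' lesions, then smallest mean CCF, then smallest cluster ID.
#'
#' Leaf clusters (present in a single lesion) do not constrain the search;
#' they are attached under the deepest cluster clonal in their lesion, and
#' are excluded from route inference downstream.
#'
#' @param matrix A `"cluster_ccf"` object (filtered).
#' @param status Clonality matrix from [call_clonality()].
#' @param roles Data.frame from [classify_cluster_roles()].
#' @param epsilon CCF comparison tolerance.
#' @param log Optional internal log buffer.
#' @return A list of class `"clone_tree"`: `parent` (named vector, `NA` for
#'   the root), `root`, `roles`, `n_mutations`.
#' @export
build_clone_tree <- function(matrix, status, roles, epsilon = 0.05,
                             log = NULL) {
  stopifnot(inherits(matrix, "cluster_ccf"))
  ccf <- matrix$ccf
  role_of <- stats::setNames(roles$role, roles$cluster_id)
  trunk <- roles$cluster_id[roles$role == "trunk"]
  if (length(trunk) != 1L) stop("build_clone_tree: roles must name one trunk")
  core <- sort(roles$cluster_id[roles$role %in% c("trunk", "branch")])
  leaves <- sort(roles$cluster_id[roles$role == "leaf"])
  if (!all(core %in% rownames(ccf)))
    stop("build_clone_tree: CCF matrix lacks cluster(s) ",
         paste(setdiff(core, rownames(ccf)), collapse = ", "))

  # relation cache over unordered core pairs
  rel <- list()
  for (i in seq_along(core)) for (j in seq_along(core)) {
    if (j <= i) next
    a <- core[i]; b <- core[j]
    rel[[paste(a, b, sep = "|")]] <-
      pairwise_relation(ccf[a, ], ccf[b, ], epsilon)
  }
  rel_of <- function(a, b) {
    r <- rel[[paste(a, b, sep = "|")]]
    if (!is.null(r)) return(r)
    r <- rel[[paste(b, a, sep = "|")]]
    switch(r, linear_a_over_b = "linear_b_over_a",
           linear_b_over_a = "linear_a_over_b", r)
  }

  free <- setdiff(core, trunk)
  # weak nesting candidates: a can be n's parent only if n never exceeds a
  weak_above <- lapply(free, function(n)
    Filter(function(a) !any(ccf[n, ] > ccf[a, ] + epsilon), setdiff(core, n)))
  names(weak_above) <- free

  # deterministic assignment order: larger (more ancestral) profiles first
  ord <- free[order(-colMeans(t(ccf[free, , drop = FALSE])), free)]
  # candidate preference: most derived feasible parent first
  pref_key <- function(a) c(max(ccf[a, ]), mean(ccf[a, ]))
  order_candidates <- function(cands) {
    if (!length(cands)) return(cands)
    keys <- t(vapply(cands, pref_key, numeric(2)))
    cands[order(keys[, 1], keys[, 2], cands)]
  }
  cand_sets <- lapply(ord, function(n) order_candidates(weak_above[[n]]))
  names(cand_sets) <- ord

  # partial-chain walk: ancestors resolvable so far (stops at unassigned)
  partial_chain <- function(parent, node) {
    out <- character(); p <- parent[[node]]
    while (!is.na(p)) { out <- c(out, p); p <- parent[[p]] }
    out
  }

  parent <- stats::setNames(rep(NA_character_, length(core)), core)
  found <- NULL
  assign_next <- function(k) {
    if (!is.null(found)) return()
    if (k > length(ord)) {
      if (tree_is_valid(parent, core, ccf, rel, epsilon)) found <<- parent
      return()
    }
    n <- ord[k]
    for (p in cand_sets[[n]]) {
      chain <- c(p, partial_chain(parent, p))
      if (n %in% chain) next  # would close a cycle
      # definite ancestors must not include a branching partner
      if (any(vapply(chain, function(a) rel_of(a, n) == "branching", logical(1))))
        next
      parent[[n]] <<- p
      assign_next(k + 1)
      parent[[n]] <<- NA_character_
      if (!is.null(found)) return()
    }
  }
  assign_next(1L)
  if (is.null(found)) {
    viol <- vapply(names(rel), function(k) rel[[k]], character(1))
    stop("build_clone_tree: no tree satisfies the pigeonhole constraints; ",
         "pairwise relations were: ",
         paste(sprintf("%s:%s", names(viol), viol), collapse = "; "))
  }
  parent <- found
  for (n in free)
    mr_log(log, "cluster %s attached under %s (most derived feasible ancestor)",
           n, parent[[n]])

  # attach leaf clusters under the deepest cluster clonal in their lesion
  n_mut <- matrix$n_mutations
  for (lf in leaves) {
    lesion <- colnames(status)[which(status[lf, ] != "absent")][1]
    clonal_here <- intersect(core, rownames(status)[status[, lesion] == "clonal"])
    depths <- stats::setNames(
      vapply(clonal_here, function(n) length(tree_ancestors(parent, n)), integer(1)),
      clonal_here)
    host <- clonal_here[order(-depths, clonal_here)][1]
    parent[[lf]] <- host
    mr_log(log, "leaf cluster %s attached under %s (deepest clonal cluster in %s)",
           lf, host, lesion)
  }

  structure(list(parent = parent, root = trunk,
                 roles = role_of[names(parent)],
                 n_mutations = if (is.null(n_mut)) NULL else
                   n_mut[intersect(names(parent), names(n_mut))]),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("Clone tree: %d clusters, root (trunk/MRCA) = %s\n",
              length(x$parent), x$root))
  kids <- tree_children(x$parent)
  show <- function(node, depth) {
    cat(sprintf("%s%s [%s]\n", strrep("  ", depth), node, x$roles[[node]]))
    for (k in sort(kids[[node]] %||% character())) show(k, depth + 1L)
  }
  show(x$root, 0L)
  invisible(x)
}

#' Per-lesion nested subclonal structure
#'
#' The machine-readable equivalent of a nested-oval plot: for each lesion,
#' the set of present clusters with their CCFs, ordered by containment
#' (tree depth). A lesion where a cluster is present while its tree parent
#' is absent violates the nesting model; with `strict = TRUE` (default)
#' this is an error, otherwise the violation is reported in the result.
#'
#' @param tree A `clone_tree`.
#' @param status Clonality matrix.
#' @param matrix A `"cluster_ccf"` object.
#' @param strict Error on nesting violations?
#' @return Named list (per lesion) of data.frames `cluster_id`, `ccf`,
#'   `status`, `depth`, each carrying a `violations` attribute.
#' @export
nested_ovals <- function(tree, status, matrix, strict = TRUE) {
  stopifnot(inherits(tree, "clone_tree"))
  depths <- tree_depths(tree)
  out <- list()
  for (les in colnames(status)) {
    present <- intersect(names(tree$parent),
                         rownames(status)[status[, les] != "absent"])
    viol <- character()
    for (n in present) {
      p <- tree$parent[[n]]
      if (!is.na(p) && !(p %in% present))
        viol <- c(viol, sprintf(
          "lesion %s: cluster %s present but its parent %s is absent",
          les, n, p))
    }
    if (length(viol) && strict)
      stop("nested_ovals: nesting violated — ", paste(viol, collapse = "; "))
    present <- present[order(depths[present], present)]
    df <- data.frame(cluster_id = present,
                     ccf = matrix$ccf[present, les],
                     status = status[present, les],
                     depth = unname(depths[present]),
                     stringsAsFactors = FALSE, row.names = NULL)
    attr(df, "violations") <- viol
    out[[les]] <- df
  }
  out
}
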