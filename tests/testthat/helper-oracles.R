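# Independent brute-force oracles and random-instance generators.
# Everything here is written without reference to the package's search
# code: plain enumeration plus direct transcription of the CCF constraints.

# climb a parent map; returns ancestors of `node` (character())
oracle_ancestors <- function(parent, node) {
  out <- character()
  p <- parent[[node]]
  while (!is.na(p)) {
    if (p %in% out) return(NULL)  # cycle
    out <- c(out, p)
    p <- parent[[p]]
  }
  out
}

# is `parent` a tree rooted at `root` (acyclic, connected)?
oracle_is_tree <- function(parent, root) {
  for (n in names(parent)) {
    if (n == root) next
    anc <- oracle_ancestors(parent, n)
    if (is.null(anc) || !(root %in% anc)) return(FALSE)
  }
  TRUE
}

# direct transcription of the pigeonhole constraints on a candidate tree
oracle_tree_ok <- function(parent, ccf, epsilon = 0.05) {
  nodes <- rownames(ccf)
  anc <- lapply(nodes, function(n) oracle_ancestors(parent, n))
  names(anc) <- nodes
  for (n in nodes) {
    p <- parent[[n]]
    if (is.na(p)) next
    if (any(ccf[n, ] > ccf[p, ] + epsilon)) return(FALSE)
  }
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (j <= i) next
    a <- nodes[i]; b <- nodes[j]
    rev_ab <- any(ccf[a, ] > ccf[b, ] + epsilon)
    rev_ba <- any(ccf[b, ] > ccf[a, ] + epsilon)
    nested <- a %in% anc[[b]] || b %in% anc[[a]]
    if (rev_ab && rev_ba && nested) return(FALSE)
    if (any(ccf[a, ] + ccf[b, ] > 1 + 2 * epsilon) && !nested) return(FALSE)
    if (!nested) {
      for (g in intersect(c(a, anc[[a]]), c(b, anc[[b]])))
        if (any(ccf[a, ] + ccf[b, ] > ccf[g, ] + 2 * epsilon)) return(FALSE)
    }
  }
  TRUE
}

# all rooted trees on the clusters of `ccf` consistent with the constraints
oracle_valid_trees <- function(ccf, epsilon = 0.05) {
  nodes <- rownames(ccf)
  trunk <- nodes[rowSums(ccf > 0.85) == ncol(ccf)]
  if (length(trunk) != 1L) return(list())
  free <- setdiff(nodes, trunk)
  if (!length(free))
    return(list(stats::setNames(NA_character_, trunk)))
  cands <- lapply(free, function(x) setdiff(nodes, x))
  idx <- rep(1L, length(free))
  out <- list()
  repeat {
    parent <- stats::setNames(
      c(NA_character_, vapply(seq_along(free), function(i)
        cands[[i]][idx[i]], character(1))),
      c(trunk, free))
    if (oracle_is_tree(parent, trunk) && oracle_tree_ok(parent, ccf, epsilon))
      out[[length(out) + 1L]] <- parent
    j <- length(free)
    while (j >= 1L) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= length(cands[[j]])) break
      idx[j] <- 1L; j <- j - 1L
    }
    if (j < 1L) break
  }
  out
}

# random well-formed CCF instance: random tree, lesion compositions as
# Dirichlet residuals over ancestor-closed clone sets; first two lesions
# carry every clone so no cluster is a leaf
random_ccf_instance <- function(n_clusters, n_lesions, jitter = 0) {
  ids <- sprintf("K%d", seq_len(n_clusters))
  parent <- stats::setNames(rep(NA_character_, n_clusters), ids)
  if (n_clusters > 1)
    for (i in 2:n_clusters) parent[[ids[i]]] <- ids[sample.int(i - 1L, 1L)]
  subtree_ccf <- function(resid) {
    ccf <- resid
    ord <- names(sort(vapply(ids, function(n)
      length(oracle_ancestors(parent, n)), integer(1)), decreasing = TRUE))
    for (n in ord) {
      p <- parent[[n]]
      if (!is.na(p)) ccf[p] <- ccf[p] + ccf[n]
    }
    ccf
  }
  resid_for <- function(members) {
    g <- stats::rgamma(length(members), shape = 1)
    r <- stats::setNames(numeric(n_clusters), ids)
    r[members] <- 0.08 + (1 - 0.08 * length(members)) * g / sum(g)
    r
  }
  mat <- matrix(0, n_clusters, n_lesions,
                dimnames = list(ids, sprintf("L%d", seq_len(n_lesions))))
  for (l in seq_len(n_lesions)) {
    members <- if (l <= 2) ids else {
      anchors <- ids[sample.int(n_clusters, sample(1:2, 1L))]
      unique(unlist(lapply(anchors, function(a)
        c(a, oracle_ancestors(parent, a)))))
    }
    mat[, l] <- subtree_ccf(resid_for(members))
  }
  if (jitter > 0) {
    noise <- matrix(stats::runif(length(mat), -jitter, jitter), nrow(mat))
    mat <- mat + noise * (mat > 0)
    mat[rownames(mat)[1], ] <- 1  # trunk stays clonal
  }
  mat <- pmin(pmax(mat, 0), 1)
  list(ccf = mat, parent = parent)
}

# --- parsimony oracle ------------------------------------------------------

# independent seeding sets: subclonal present clusters plus clonal clusters
# with no clonal descendant present (descent per the provided parent map)
oracle_seeding_set <- function(lesion, status, parent, nonleaf) {
  st <- status[nonleaf, lesion]
  clonal <- nonleaf[st == "clonal"]
  sub <- nonleaf[st == "subclonal"]
  deepest <- Filter(function(n) {
    desc_clonal <- Filter(function(x) n %in% oracle_ancestors(parent, x), clonal)
    length(desc_clonal) == 0
  }, clonal)
  sort(unique(c(sub, deepest)))
}

oracle_layer_ok <- function(from, to) {
  rk <- c("T" = 0, "P" = 1, "I" = 2, "C" = 3, "LM" = 4)
  if (to == "LM") return(TRUE)
  if (from == "LM") return(FALSE)
  rk[[from]] <= rk[[to]]
}

# exhaustive minimum of metastasis-to-metastasis routes over full-coverage
# acyclic source assignments; NA when no such assignment exists
oracle_min_met_routes <- function(status, parent, lesions, nonleaf,
                                  max_grid = 2e5) {
  primary <- lesions$lesion_id[lesions$layer == "T"]
  mets <- lesions$lesion_id[lesions$layer != "T"]
  layer <- stats::setNames(lesions$layer, lesions$lesion_id)
  cands <- lapply(mets, function(m) {
    set <- oracle_seeding_set(m, status, parent, nonleaf)
    Filter(function(l) l != m && oracle_layer_ok(layer[[l]], layer[[m]]) &&
             all(status[set, l] != "absent"), lesions$lesion_id)
  })
  names(cands) <- mets
  if (any(lengths(cands) == 0)) return(NA_integer_)
  if (prod(lengths(cands)) > max_grid) return(NA_integer_)
  idx <- rep(1L, length(mets))
  best <- NA_integer_
  repeat {
    src <- stats::setNames(vapply(seq_along(mets), function(i)
      cands[[i]][idx[i]], character(1)), mets)
    acyclic <- TRUE
    for (m in mets) {
      seen <- character(); v <- m
      while (v %in% mets) {
        if (src[[v]] %in% seen || src[[v]] == m) { acyclic <- FALSE; break }
        seen <- c(seen, v)
        v <- src[[v]]
      }
      if (!acyclic) break
    }
    if (acyclic) {
      k <- sum(src %in% mets)
      if (is.na(best) || k < best) best <- k
    }
    j <- length(mets)
    while (j >= 1L) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= length(cands[[j]])) break
      idx[j] <- 1L; j <- j - 1L
    }
    if (j < 1L) break
  }
  best
}

# small status/clonality fixture builder used across route tests
status_matrix <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  m
}

make_tree <- function(parent_map, roles = NULL, n_mutations = NULL) {
  root <- names(parent_map)[is.na(parent_map)]
  if (is.null(roles)) {
    roles <- stats::setNames(
      ifelse(names(parent_map) == root, "trunk", "branch"), names(parent_map))
  }
  structure(list(parent = parent_map, root = root, roles = roles,
                 n_mutations = n_mutations),
            class = "clone_tree")
}
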