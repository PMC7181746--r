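#' Seeding clone set of a lesion
#'
#' The clones whose cells founded (or persist in) a lesion, read from the
#' clonality statuses and the clone tree. A clone has cells of its own in
#' the lesion when not all of its cells have acquired deeper cluster
#' mutations; operationally the seeding set collects every present non-leaf
#' cluster that is subclonal in the lesion, plus each clonal cluster with no
#' clonal descendant present (the residual parental clone). Leaf clusters
#' (private to the lesion) arose in situ and are excluded.
#'
#' A metastasis in which every present non-leaf cluster is clonal was
#' founded by cells of a single clone (*monoclonal* seeding); one or more
#' subclonal clusters imply a founding mixture of subclones (*multiclonal*
#' seeding).
#'
#' @param lesion_id Lesion to evaluate.
#' @param tree A `clone_tree`.
#' @param status Clonality matrix.
#' @return List of class `"seeding_clone_set"`: `lesion_id`, `clones`
#'   (character vector), `classification` (`"monoclonal"`/`"multiclonal"`).
#' @export
seeding_clone_set <- function(lesion_id, tree, status) {
  stopifnot(inherits(tree, "clone_tree"))
  if (!lesion_id %in% colnames(status))
    stop("unknown lesion: ", lesion_id)
  nonleaf <- names(tree$parent)[tree$roles != "leaf"]
  st <- status[nonleaf, lesion_id]
  present <- nonleaf[st != "absent"]
  if (!length(present))
    stop("lesion ", lesion_id, " has no present non-leaf clusters")
  subclonal <- nonleaf[st == "subclonal"]
  clonal <- nonleaf[st == "clonal"]
  deepest_clonal <- Filter(function(n)
    !any(tree_descendants(tree$parent, n) %in% clonal), clonal)
  clones <- sort(unique(c(subclonal, deepest_clonal)))
  structure(list(lesion_id = lesion_id, clones = clones,
                 classification = if (length(subclonal)) "multiclonal"
                                  else "monoclonal"),
            class = "seeding_clone_set")
}

#' Candidate source lesions for a metastasis
#'
#' A lesion qualifies as the source of a metastasis when it contains every
#' clone of the metastasis' seeding set (status not absent) and the route
#' respects the layer order: lymph flows outward only (a lymphatic lesion
#' can be seeded from the same or a more proximal layer, never from a more
#' distal one), any layer may seed a liver metastasis, and liver metastases
#' never seed back into the lymphatic network.
#'
#' @param target A [seeding_clone_set()] for the metastasis.
#' @param lesions Data.frame with `lesion_id`, `layer`.
#' @param status Clonality matrix.
#' @return Character vector of candidate lesion IDs (sorted). Errors when
#'   empty, naming the missing clones (a model-assumption violation).
#' @export
candidate_sources <- function(target, lesions, status) {
  stopifnot(inherits(target, "seeding_clone_set"))
  cands <- .candidate_sources(target$clones, target$lesion_id, lesions, status)
  if (!length(cands)) {
    absent_where <- vapply(target$clones, function(cl)
      sum(status[cl, setdiff(colnames(status), target$lesion_id)] != "absent"),
      numeric(1))
    stop("no candidate source for ", target$lesion_id,
         ": no other lesion at an allowed layer carries clone(s) ",
         paste(names(absent_where)[absent_where == min(absent_where)],
               collapse = ", "))
  }
  cands
}

.candidate_sources <- function(clones, target_id, lesions, status,
                               exclude = character()) {
  target_layer <- lesions$layer[lesions$lesion_id == target_id]
  ok <- vapply(seq_len(nrow(lesions)), function(i) {
    l <- lesions$lesion_id[i]
    if (l == target_id || l %in% exclude) return(FALSE)
    if (!layer_route_ok(lesions$layer[i], target_layer)) return(FALSE)
    all(status[clones, l] != "absent")
  }, logical(1))
  sort(lesions$lesion_id[ok])
}

#' Color cluster of a route
#'
#' Routes on a metastatic map are colored by the smallest involved
#' subclone: the most-derived (deepest) clone of the seeding set. Ties (for
#' example sister clones at equal depth) break by cluster ID.
#'
#' @param clones Character vector of seeding clone IDs (non-empty).
#' @param tree A `clone_tree`.
#' @return A single cluster ID.
#' @export
color_route <- function(clones, tree) {
  if (!length(clones)) stop("color_route: empty seeding clone set")
  depths <- tree_depths(tree)[clones]
  clones[order(-depths, clones)][1]
}

# --- inference internals ---------------------------------------------------

# first directed cycle in the functional source map (NA / non-met sources
# terminate walks); returns sorted member ids or NULL
.find_cycle <- function(source_of) {
  nodes <- names(source_of)
  state <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 stack, 2 done
  for (start in nodes) {
    if (state[[start]] != 0L) next
    path <- character()
    v <- start
    while (!is.na(v) && v %in% nodes && state[[v]] != 2L) {
      if (state[[v]] == 1L) {
        cyc <- path[seq(which(path == v), length(path))]
        return(sort(cyc))
      }
      state[[v]] <- 1L
      path <- c(path, v)
      v <- source_of[[v]]
    }
    state[path] <- 2L
  }
  NULL
}

# strongly connected component containing `seed` in the directed graph
# given as a named list of out-neighbors
.scc_of <- function(seed, edges) {
  reach <- function(from) {
    seen <- character(); frontier <- from
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(edges[frontier], use.names = FALSE)), seen)
      seen <- c(seen, frontier)
      frontier <- setdiff(nxt, seen)
    }
    unique(seen)
  }
  fwd <- reach(seed)
  back <- Filter(function(v) seed %in% reach(v), fwd)
  sort(unique(c(seed, back)))
}

#' Infer the parsimonious metastatic map
#'
#' Assigns exactly one seeding route to every metastasis under the model
#' assumptions: unidirectional lymph flow (no reverse routes), vanished
#' clones are not considered (a source's present-day clone content stands
#' in for its history), and migrations are rare, so each metastasis stems
#' from a single seeding event in which all shared subclones migrated
#' jointly. Sources are chosen to minimize the number of
#' metastasis-to-metastasis routes (the primary tumor is preferred whenever
#' it contains the full seeding set); among metastasis candidates, the one
#' sharing the deepest clone with the target wins, then the smallest lesion
#' ID.
#'
#' When candidate constraints force a cycle — a group of lesions bound by
#' clones private to the group — the member in which those private clones
#' are all subclonal is taken as the lesion where they arose in situ; it is
#' re-sourced externally (treating the private clones as in-situ
#' originations) and the rest of the group descends from it. Groups with
#' identical clonal composition are genuinely direction-free; they are
#' resolved by convention (the lexicographically largest lesion ID is
#' seeded externally and reseeds down the chain) and reported in
#' `ambiguity_groups`.
#'
#' @param dataset A [patient_dataset()] (only the lesion metadata is used).
#' @param tree A `clone_tree`.
#' @param status Clonality matrix.
#' @param log Optional internal log buffer.
#' @return A list of class `"metastatic_map"`: `patient_id`, `routes`
#'   (data.frame), `ambiguity_groups` (list of character vectors),
#'   `lesions`, `log`.
#' @export
infer_metastatic_map <- function(dataset, tree, status, log = NULL) {
  stopifnot(inherits(tree, "clone_tree"))
  lesions <- dataset$lesions
  own_log <- is.null(log)
  if (own_log) log <- mr_new_log()
  primary <- lesions$lesion_id[lesions$layer == "T"]
  mets <- lesions$lesion_id[lesions$layer != "T"]
  mets <- mets[order(layer_rank(lesions$layer[match(mets, lesions$lesion_id)]), mets)]
  nonleaf <- names(tree$parent)[tree$roles != "leaf"]
  depths <- tree_depths(tree)

  sets <- lapply(mets, seeding_clone_set, tree = tree, status = status)
  names(sets) <- mets

  present_in <- function(l) nonleaf[status[nonleaf, l] != "absent"]
  shared_depth <- function(m, s) {
    shared <- intersect(present_in(m), present_in(s))
    if (!length(shared)) return(-1L)
    max(depths[shared])
  }
  order_met_cands <- function(m, cands) {
    if (length(cands) <= 1L) return(cands)
    sd <- vapply(cands, function(s) shared_depth(m, s), numeric(1))
    cands[order(-sd, cands)]
  }

  cand <- lapply(mets, function(m)
    .candidate_sources(sets[[m]]$clones, m, lesions, status))
  names(cand) <- mets

  source_of <- stats::setNames(rep(NA_character_, length(mets)), mets)
  clones_of <- sets_to <- stats::setNames(vector("list", length(mets)), mets)
  for (m in mets) clones_of[[m]] <- sets[[m]]$clones
  insitu_of <- stats::setNames(vector("list", length(mets)), mets)
  ambiguity_groups <- list()

  # best externally-relaxed source for m: a lesion outside `exclude` whose
  # missing clones ("uncovered") are all subclonal in m, i.e. plausibly
  # arose in m after seeding.  Preference: fewest uncovered, then the
  # primary, then deepest shared clone, then lesion ID.
  relaxed_choice <- function(m, exclude = character()) {
    target_layer <- lesions$layer[lesions$lesion_id == m]
    opts <- list()
    for (i in seq_len(nrow(lesions))) {
      l <- lesions$lesion_id[i]
      if (l == m || l %in% exclude) next
      if (!layer_route_ok(lesions$layer[i], target_layer)) next
      uncovered <- sets[[m]]$clones[status[sets[[m]]$clones, l] == "absent"]
      if (any(status[uncovered, m] == "clonal")) next  # a clonal founder must be imported
      opts[[l]] <- uncovered
    }
    if (!length(opts)) return(NULL)
    ls <- names(opts)
    key <- order(lengths(opts),
                 ls != primary,
                 -vapply(ls, function(s) shared_depth(m, s), numeric(1)),
                 ls)
    list(source = ls[key[1]], uncovered = opts[[ls[key[1]]]])
  }

  # ---- initial assignment ----
  for (m in mets) {
    if (primary %in% cand[[m]]) {
      source_of[[m]] <- primary
      mr_log(log, "%s: seeded by primary %s (full seeding set %s present there)",
             m, primary, paste(sets[[m]]$clones, collapse = ","))
    }
  }
  for (m in mets[is.na(source_of)]) {
    mc <- setdiff(cand[[m]], primary)
    if (length(mc)) {
      pick <- order_met_cands(m, mc)[1]
      source_of[[m]] <- pick
      mr_log(log, "%s: primary lacks the seeding set; tentative source %s (deepest shared clone, then lesion ID)",
             m, pick)
    } else {
      rc <- relaxed_choice(m)
      if (is.null(rc))
        stop("infer_metastatic_map: no feasible source for ", m,
             "; seeding set ", paste(sets[[m]]$clones, collapse = ","),
             " cannot be explained under the model assumptions")
      source_of[[m]] <- rc$source
      insitu_of[[m]] <- rc$uncovered
      clones_of[[m]] <- setdiff(sets[[m]]$clones, rc$uncovered)
      mr_log(log, "%s: no lesion carries the full seeding set; source %s with in-situ origination of %s",
             m, rc$source, paste(rc$uncovered, collapse = ","))
    }
  }

  # ---- cycle resolution ----
  identical_composition <- function(group) {
    ref <- status[nonleaf, group[1]]
    all(vapply(group[-1], function(g)
      identical(unname(status[nonleaf, g]), unname(ref)), logical(1)))
  }
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 10L * length(mets) + 10L)
      stop("infer_metastatic_map: cycle resolution did not converge")
    cyc <- .find_cycle(source_of)
    if (is.null(cyc)) break
    # candidate edges include every feasible relaxed source, so a family of
    # lesions bound by in-situ marker clones resolves as one group
    feasible_relaxed_mets <- function(m) {
      target_layer <- lesions$layer[lesions$lesion_id == m]
      Filter(function(l) {
        i <- match(l, lesions$lesion_id)
        if (l == m || !layer_route_ok(lesions$layer[i], target_layer))
          return(FALSE)
        uncovered <- sets[[m]]$clones[status[sets[[m]]$clones, l] == "absent"]
        !any(status[uncovered, m] == "clonal")
      }, mets)
    }
    edges <- lapply(mets, function(m)
      unique(c(setdiff(cand[[m]], primary), source_of[[m]],
               feasible_relaxed_mets(m))))
    names(edges) <- mets
    edges <- lapply(edges, function(v) intersect(v, mets))
    scc <- .scc_of(cyc[1], edges)
    scc <- sort(intersect(scc, mets))
    scc <- scc[source_of[scc] %in% mets]  # primary-sourced lesions stay put
    mr_log(log, "candidate cycle among {%s}", paste(scc, collapse = ", "))

    # 1) exhaustive acyclic re-assignment within the group's candidates
    opt_sets <- lapply(scc, function(m) {
      mc <- order_met_cands(m, setdiff(cand[[m]], primary))
      if (!length(mc) && !is.null(insitu_of[[m]])) mc <- source_of[[m]]
      mc
    })
    names(opt_sets) <- scc
    solved <- FALSE
    if (all(lengths(opt_sets) > 0) && prod(lengths(opt_sets)) <= 100000) {
      grid_idx <- rep(1L, length(scc))
      repeat {
        trial <- source_of
        for (i in seq_along(scc)) trial[[scc[i]]] <- opt_sets[[scc[i]]][grid_idx[i]]
        if (is.null(.find_cycle(trial))) {
          source_of <- trial
          solved <- TRUE
          mr_log(log, "cycle broken by re-assignment within candidates: %s",
                 paste(sprintf("%s<-%s", scc, source_of[scc]), collapse = ", "))
          break
        }
        j <- length(scc)
        while (j >= 1) {
          grid_idx[j] <- grid_idx[j] + 1L
          if (grid_idx[j] <= length(opt_sets[[scc[j]]])) break
          grid_idx[j] <- 1L; j <- j - 1
        }
        if (j < 1) break
      }
    }
    if (solved) next

    # 2) escape: one member is re-sourced outside the group
    escapes <- lapply(scc, function(m) relaxed_choice(m, exclude = scc))
    names(escapes) <- scc
    feas <- scc[!vapply(escapes, is.null, logical(1))]

    if (!length(feas) || identical_composition(scc)) {
      if (!identical_composition(scc))
        stop("infer_metastatic_map: unresolvable cycle among ",
             paste(scc, collapse = ", "),
             " and no member can be re-sourced externally")
      # direction-free group: canonical convention, flagged as ambiguous
      group <- sort(scc, decreasing = TRUE)
      head_m <- group[1]
      private <- nonleaf[vapply(nonleaf, function(cl)
        all(status[cl, setdiff(colnames(status), scc)] == "absent") &&
          any(status[cl, scc] != "absent"), logical(1))]
      masked_status <- status
      masked_status[private, ] <- "absent"
      head_set <- seeding_clone_set(head_m, tree, masked_status)
      ext <- .candidate_sources(head_set$clones, head_m, lesions, masked_status,
                                exclude = scc)
      if (!length(ext))
        stop("infer_metastatic_map: ambiguity group ",
             paste(scc, collapse = ","), " has no external source even after",
             " masking its private clones")
      pick <- if (primary %in% ext) primary else order_met_cands(head_m, ext)[1]
      source_of[[head_m]] <- pick
      clones_of[[head_m]] <- head_set$clones
      insitu_of[[head_m]] <- intersect(sets[[head_m]]$clones, private)
      for (i in seq_along(group)[-1]) source_of[[group[i]]] <- group[i - 1]
      ambiguity_groups <- c(ambiguity_groups, list(sort(scc)))
      mr_log(log, "lesions {%s} have identical clonal composition; conventional resolution %s<-%s then chain %s",
             paste(scc, collapse = ", "), head_m, pick,
             paste(rev(group), collapse = "->"))
    } else {
      # choose the origin (the member re-sourced externally) minimizing the
      # total number of in-situ clone originations the whole group then
      # needs; the member whose group-binding clones are still subclonal
      # (i.e. arose there recently) is preferred on ties, then lesion ID
      total_cost <- vapply(feas, function(o) {
        events <- escapes[[o]]$uncovered  # clusters arising in situ at o
        cost <- length(events)
        for (m in setdiff(scc, o)) {
          if (length(cand[[m]])) next  # full coverage available at no cost
          rc <- relaxed_choice(m)
          if (is.null(rc)) return(1e6)
          cost <- cost + length(rc$uncovered)
          # a cluster can only originate once: hypotheses that make the
          # same cluster arise in two lesions are heavily penalized
          cost <- cost + 1000 * sum(rc$uncovered %in% events)
          events <- c(events, rc$uncovered)
        }
        cost
      }, numeric(1))
      all_sub <- vapply(feas, function(m)
        all(status[escapes[[m]]$uncovered, m] == "subclonal"), logical(1))
      origin <- feas[order(total_cost, !all_sub, feas)][1]
      esc <- escapes[[origin]]
      source_of[[origin]] <- esc$source
      insitu_of[[origin]] <- esc$uncovered
      clones_of[[origin]] <- setdiff(sets[[origin]]$clones, esc$uncovered)
      mr_log(log, "%s re-sourced externally to %s; clone(s) %s treated as in-situ originations",
             origin, esc$source, paste(esc$uncovered, collapse = ","))
      # let the remaining members re-pick their preferred candidate
      for (m in setdiff(scc, origin)) {
        mc <- order_met_cands(m, setdiff(cand[[m]], primary))
        if (length(mc)) source_of[[m]] <- mc[1]
      }
    }
  }

  if (!is.null(.find_cycle(source_of)))
    stop("infer_metastatic_map: internal error — residual cycle")

  routes <- data.frame(
    source_lesion = unname(source_of[mets]),
    target_lesion = mets,
    seeding_clones = vapply(mets, function(m)
      paste(sort(clones_of[[m]]), collapse = ";"), character(1)),
    n_seeding_clones = vapply(mets, function(m)
      length(clones_of[[m]]), integer(1)),
    seeding_class = vapply(mets, function(m)
      sets[[m]]$classification, character(1)),
    color_cluster = vapply(mets, function(m)
      color_route(clones_of[[m]], tree), character(1)),
    in_situ_clones = vapply(mets, function(m)
      paste(sort(insitu_of[[m]] %||% character()), collapse = ";"), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  routes$mode <- vapply(seq_len(nrow(routes)), function(i)
    classify_mode(routes$source_lesion[i], routes$target_lesion[i], lesions),
    character(1))

  structure(list(patient_id = dataset$patient_id %||% "patient",
                 routes = routes,
                 ambiguity_groups = ambiguity_groups,
                 lesions = lesions,
                 log = mr_log_lines(log)),
            class = "metastatic_map")
}

#' @export
print.metastatic_map <- function(x, ...) {
  cat(sprintf("Metastatic map for %s: %d routes\n", x$patient_id,
              nrow(x$routes)))
  for (i in seq_len(nrow(x$routes)))
    cat(sprintf("  %s -> %s  [%s, %s, color %s]\n",
                x$routes$source_lesion[i], x$routes$target_lesion[i],
                x$routes$seeding_class[i], x$routes$mode[i],
                x$routes$color_cluster[i]))
  if (length(x$ambiguity_groups))
    cat("  ambiguity groups:",
        paste(vapply(x$ambiguity_groups, paste, character(1), collapse = "/"),
              collapse = "; "), "\n")
  invisible(x)
}
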