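#' Simulation configuration
#'
#' Parameters of the synthetic patient generator. Defaults mirror the study
#' design the package targets: 2 regions from the primary tumor and from
#' each liver metastasis, single-region lymph node metastases across the P,
#' I and C layers, exome sequencing at an average depth of 264X, and about
#' a third of metastases reseeded by another metastasis rather than by the
#' primary.
#'
#' @param n_clusters Number of mutation clusters before in-situ marker
#'   subclones (>= 1). Default 7.
#' @param mutations_per_cluster Inclusive range for per-cluster mutation
#'   counts, drawn uniformly. Default `c(5, 40)` (all clusters survive the
#'   default size filter).
#' @param n_lesions_per_layer Named counts over `P`, `I`, `C`, `LM`.
#' @param n_regions_primary Regions sampled from the primary (2-5 in
#'   practice). Default 2.
#' @param n_regions_lm Regions per liver metastasis. Default 2.
#' @param depth Sequencing depth per region. Default 264.
#' @param purity Tumor purity of every sample. Default 0.7.
#' @param fraction_metastasis_seeded Probability that a metastasis is
#'   seeded by an eligible earlier metastasis rather than the primary.
#'   Default 0.35.
#' @param private_marker_probability Probability that a
#'   metastasis-to-metastasis seeding is accompanied by a fresh private
#'   marker subclone in the source (1 keeps the regime identifiable;
#'   without a marker, reseeding is indistinguishable from primary seeding
#'   and parsimony will — correctly — prefer the primary). Default 1.
#' @param marker_mutations Inclusive range for marker-cluster mutation
#'   counts. Default `c(5, 15)`.
#' @param region_concentration Dirichlet concentration for spatial
#'   perturbation of clone fractions across regions of a multi-region
#'   lesion (larger = more homogeneous). Default 10.
#' @param noise `"binomial"` (read-count resampling at `depth`) or
#'   `"none"` (exact CCFs).
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_clusters = 7L,
                              mutations_per_cluster = c(5L, 40L),
                              n_lesions_per_layer = c(P = 3L, I = 2L, C = 1L, LM = 1L),
                              n_regions_primary = 2L,
                              n_regions_lm = 2L,
                              depth = 264L,
                              purity = 0.7,
                              fraction_metastasis_seeded = 0.35,
                              private_marker_probability = 1,
                              marker_mutations = c(5L, 15L),
                              region_concentration = 10,
                              noise = c("binomial", "none")) {
  noise <- match.arg(noise)
  stopifnot(n_clusters >= 1, depth >= 1, purity > 0, purity <= 1,
            fraction_metastasis_seeded >= 0, fraction_metastasis_seeded <= 1,
            private_marker_probability >= 0, private_marker_probability <= 1,
            region_concentration > 0)
  layers <- c(P = 0L, I = 0L, C = 0L, LM = 0L)
  layers[names(n_lesions_per_layer)] <- as.integer(n_lesions_per_layer)
  structure(list(n_clusters = as.integer(n_clusters),
                 mutations_per_cluster = as.integer(mutations_per_cluster),
                 n_lesions_per_layer = layers,
                 n_regions_primary = as.integer(n_regions_primary),
                 n_regions_lm = as.integer(n_regions_lm),
                 depth = as.integer(depth), purity = purity,
                 fraction_metastasis_seeded = fraction_metastasis_seeded,
                 private_marker_probability = private_marker_probability,
                 marker_mutations = as.integer(marker_mutations),
                 region_concentration = region_concentration,
                 noise = noise),
            class = "simulation_config")
}

#' Simulate a clone tree
#'
#' Random recursive tree: the trunk first, then each new cluster attaches
#' to a uniformly chosen existing node. Mutation counts are drawn uniformly
#' from the configured range (at or above the default retention threshold,
#' so no simulated cluster is filtered out).
#'
#' @param config A [simulation_config()].
#' @return A `clone_tree` (roles provisional: trunk plus branch).
#' @export
simulate_clone_tree <- function(config = simulation_config()) {
  k <- config$n_clusters
  ids <- sprintf("C%02d", seq_len(k))
  parent <- stats::setNames(rep(NA_character_, k), ids)
  for (i in seq_len(k)[-1])
    parent[[ids[i]]] <- ids[sample.int(i - 1L, 1L)]
  rng <- config$mutations_per_cluster
  n_mut <- stats::setNames(
    sample(seq(rng[1], rng[2]), k, replace = TRUE), ids)
  roles <- stats::setNames(c("trunk", rep("branch", k - 1L)), ids)
  structure(list(parent = parent, root = ids[1], roles = roles,
                 n_mutations = n_mut),
            class = "clone_tree")
}

# residual clone fractions -> per-cluster CCFs (subtree sums), bottom-up
.resid_to_ccf <- function(resid, parent) {
  nodes <- names(parent)
  depth <- vapply(nodes, function(n) {
    d <- 0L; p <- parent[[n]]
    while (!is.na(p)) { d <- d + 1L; p <- parent[[p]] }
    d
  }, integer(1))
  ccf <- stats::setNames(vapply(nodes, function(n)
    if (n %in% names(resid)) resid[[n]] else 0, numeric(1)), nodes)
  for (n in nodes[order(-depth)]) {
    p <- parent[[n]]
    if (!is.na(p)) ccf[p] <- ccf[p] + ccf[n]
  }
  ccf
}

#' Simulate a metastatic seeding history
#'
#' Builds the ground truth for one patient. The primary tumor receives all
#' clones with random residual fractions (the trunk clone keeps a fixed
#' residual of 0.30, so no subclone approaches clonality in the primary;
#' every other clone keeps at least a small residual, so all clones remain
#' detectable). Metastases are then created in layer order; each is seeded
#' in a single event from one eligible existing lesion — the primary with
#' probability `1 - fraction_metastasis_seeded` — by a random non-empty
#' clone set of the source (joint migration of the shared subclones). A
#' metastasis-to-metastasis seeding carves, with probability
#' `private_marker_probability`, a fresh marker subclone out of the source
#' that is shared exclusively between source and target; when the source
#' has too little residual clone mass to host a marker, the event falls
#' back to primary seeding (logged), keeping the default regime
#' identifiable. Layer constraints are never violated by construction.
#'
#' @param tree A `clone_tree` from [simulate_clone_tree()].
#' @param config A [simulation_config()].
#' @return A list of class `"ground_truth"`: `tree` (possibly extended by
#'   marker clusters), `lesions`, `routes` (true source/target/clones/
#'   class), `composition` (per-lesion residual clone fractions), `log`.
#' @export
simulate_metastatic_history <- function(tree, config = simulation_config()) {
  log <- mr_new_log()
  parent <- tree$parent
  n_mut <- tree$n_mutations
  ids <- names(parent)
  trunk <- tree$root
  k <- length(ids)

  resid_T <- stats::setNames(numeric(k), ids)
  if (k == 1L) {
    resid_T[trunk] <- 1
  } else {
    resid_T[trunk] <- 0.30
    floor_r <- min(0.08, 0.7 / (k - 1) * 0.6)
    g <- stats::rgamma(k - 1L, shape = 1)
    resid_T[setdiff(ids, trunk)] <-
      floor_r + (0.7 - floor_r * (k - 1L)) * g / sum(g)
  }
  composition <- list("T" = resid_T)

  layer_of <- c("T" = "T")
  mets <- character()
  for (layer in c("P", "I", "C", "LM")) {
    nl <- config$n_lesions_per_layer[[layer]]
    if (nl > 0) {
      lid <- paste0(layer, seq_len(nl))
      mets <- c(mets, lid)
      layer_of[lid] <- layer
    }
  }

  new_marker <- function(src, n_existing) {
    resid <- composition[[src]]
    host <- names(resid)[which.max(resid)]
    if (resid[host] < 0.25) return(NULL)
    x <- sprintf("C%02d", n_existing + 1L)
    carve <- min(0.3, 0.45 * resid[host])
    list(id = x, host = host, carve = carve)
  }

  routes <- list()
  markers_of <- list()  # marker clusters carved in each lesion, per target
  for (m in mets) {
    lay <- layer_of[[m]]
    elig <- Filter(function(s) {
      sl <- layer_of[[s]]
      if (lay == "LM") TRUE else sl != "LM" && layer_rank(sl) <= layer_rank(lay)
    }, names(composition)[-1])
    src <- "T"
    marker <- NULL
    if (length(elig) &&
        stats::runif(1) < config$fraction_metastasis_seeded) {
      cand_src <- sort(elig)[sample.int(length(elig), 1L)]
      want_marker <- stats::runif(1) < config$private_marker_probability
      if (want_marker) {
        marker <- new_marker(cand_src, length(ids))
        if (is.null(marker)) {
          mr_log(log, "%s: source %s cannot host a marker subclone; falling back to primary seeding",
                 m, cand_src)
        } else {
          src <- cand_src
        }
      } else {
        src <- cand_src
      }
    }
    if (!is.null(marker) && src != "T") {
      # marker subclone arises in the source before the seeding event
      x <- marker$id
      parent[[x]] <- marker$host
      rng <- config$marker_mutations
      n_mut[[x]] <- sample(seq(rng[1], rng[2]), 1L)
      ids <- c(ids, x)
      for (l in names(composition)) {
        composition[[l]] <- c(composition[[l]], stats::setNames(0, x))
      }
      composition[[src]][marker$host] <- composition[[src]][marker$host] - marker$carve
      composition[[src]][x] <- marker$carve
      markers_of[[src]] <- c(markers_of[[src]], x)
      mr_log(log, "%s: marker subclone %s (child of %s) arises in %s",
             m, x, marker$host, src)
    }

    # markers carved for earlier targets stay private to those routes:
    # excluding them from later seeding sets keeps each marker shared
    # exclusively between its source and its own target
    pool <- names(composition[[src]])[composition[[src]] >= 0.10]
    pool <- setdiff(pool, setdiff(markers_of[[src]],
                                  if (!is.null(marker)) marker$id else character()))
    size <- sample(1:3, 1L, prob = c(0.3, 0.5, 0.2))
    if (!is.null(marker) && src != "T") {
      extra <- setdiff(pool, marker$id)
      S <- c(marker$id,
             if (size > 1 && length(extra))
               sort(extra)[sample.int(length(extra), min(size - 1L, length(extra)))])
    } else {
      size <- min(size, length(pool))
      S <- sort(pool)[sample.int(length(pool), size)]
    }
    fr <- if (length(S) == 1L) 1 else if (length(S) == 2L) {
      u <- stats::runif(1, 0.3, 0.7); c(u, 1 - u)
    } else {
      repeat {
        g <- stats::rgamma(length(S), shape = 1); d <- g / sum(g)
        if (all(d >= 0.22 & d <= 0.56)) break
      }
      d
    }
    comp_m <- stats::setNames(numeric(length(ids)), ids)
    comp_m[S] <- fr
    composition[[m]] <- comp_m
    routes[[m]] <- list(source = src, target = m, clones = sort(S))
    mr_log(log, "%s: seeded from %s by clone(s) %s", m, src,
           paste(sort(S), collapse = ","))
  }

  # pad earlier compositions to the final cluster universe
  composition <- lapply(composition, function(r) {
    out <- stats::setNames(numeric(length(ids)), ids)
    out[names(r)] <- r
    out
  })

  ccfs <- vapply(names(composition), function(l)
    .resid_to_ccf(composition[[l]], parent), numeric(length(ids)))
  rownames(ccfs) <- ids
  n_present <- rowSums(ccfs > 0.05)
  true_class <- vapply(mets, function(m) {
    pres <- ids[ccfs[, m] > 0.05 & n_present >= 2]  # non-leaf, present
    if (all(ccfs[pres, m] > 0.85)) "monoclonal" else "multiclonal"
  }, character(1))

  lesions <- data.frame(lesion_id = c("T", mets),
                        layer = unname(layer_of[c("T", mets)]),
                        stringsAsFactors = FALSE)
  routes_df <- data.frame(
    source_lesion = vapply(routes, `[[`, character(1), "source"),
    target_lesion = vapply(routes, `[[`, character(1), "target"),
    seeding_clones = vapply(routes, function(r)
      paste(r$clones, collapse = ";"), character(1)),
    seeding_class = unname(true_class[vapply(routes, `[[`, character(1), "target")]),
    stringsAsFactors = FALSE, row.names = NULL)

  out_tree <- structure(list(parent = parent, root = trunk,
                             roles = stats::setNames(
                               ifelse(names(parent) == trunk, "trunk", "branch"),
                               names(parent)),
                             n_mutations = n_mut[names(parent)]),
                        class = "clone_tree")
  structure(list(tree = out_tree, lesions = lesions, routes = routes_df,
                 composition = composition, true_ccf = ccfs,
                 config = config, log = mr_log_lines(log)),
            class = "ground_truth")
}

#' Validate a simulated ground truth
#'
#' Independent audit of the generator's own invariants: every metastasis
#' has exactly one seeding route; no route violates the layer order; every
#' seeding clone is present in its source (joint migration); per-lesion
#' clone fractions respect the tree nesting (child CCF never exceeds its
#' parent's) and residuals sum to 1 in seeded lesions.
#'
#' @param truth A `"ground_truth"`.
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_ground_truth <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  r <- truth$routes
  mets <- truth$lesions$lesion_id[truth$lesions$layer != "T"]
  if (!setequal(r$target_lesion, mets) || anyDuplicated(r$target_lesion))
    stop("ground truth: metastases must have exactly one route each")
  for (i in seq_len(nrow(r))) {
    sl <- truth$lesions$layer[truth$lesions$lesion_id == r$source_lesion[i]]
    tl <- truth$lesions$layer[truth$lesions$lesion_id == r$target_lesion[i]]
    if (!layer_route_ok(sl, tl))
      stop("ground truth: route ", r$source_lesion[i], "->",
           r$target_lesion[i], " violates the layer order")
    clones <- strsplit(r$seeding_clones[i], ";", fixed = TRUE)[[1]]
    if (any(truth$true_ccf[clones, r$source_lesion[i]] <= 0))
      stop("ground truth: seeding clone absent from source in route ",
           r$source_lesion[i], "->", r$target_lesion[i])
  }
  parent <- truth$tree$parent
  for (l in names(truth$composition)) {
    if (abs(sum(truth$composition[[l]]) - 1) > 1e-8)
      stop("ground truth: residual fractions of ", l, " do not sum to 1")
    for (n in names(parent)) {
      p <- parent[[n]]
      if (!is.na(p) && truth$true_ccf[n, l] > truth$true_ccf[p, l] + 1e-8)
        stop("ground truth: nesting violated in ", l, " at cluster ", n)
    }
  }
  invisible(TRUE)
}

#' Simulate sequencing observations of a ground truth
#'
#' Emits the per-mutation, per-sample CCF table a PyClone-style workflow
#' would produce. Multi-region lesions (primary, liver metastases) get
#' Dirichlet-perturbed per-region clone fractions to emulate spatial
#' heterogeneity; single-region lesions are observed as-is. With binomial
#' noise, each mutation's variant reads are drawn as
#' `Binomial(depth, purity * CCF / 2)` (diploid loci, one mutated copy) and
#' the CCF is back-converted with [ccf_from_counts()]; with `noise =
#' "none"` the true CCFs are emitted exactly.
#'
#' @param truth A `"ground_truth"`.
#' @param config A [simulation_config()] (defaults to the truth's own).
#' @return A [patient_dataset()].
#' @export
simulate_observations <- function(truth, config = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  config <- config %||% truth$config
  parent <- truth$tree$parent
  ids <- names(parent)
  n_mut <- truth$tree$n_mutations

  regions <- list()
  for (i in seq_len(nrow(truth$lesions))) {
    l <- truth$lesions$lesion_id[i]
    nr <- if (truth$lesions$layer[i] == "T") config$n_regions_primary
          else if (truth$lesions$layer[i] == "LM") config$n_regions_lm
          else 1L
    sid <- if (nr == 1L) l else paste0(l, "_R", seq_len(nr))
    regions[[l]] <- sid
  }
  region_df <- data.frame(
    sample_id = unlist(regions, use.names = FALSE),
    lesion_id = rep(names(regions), lengths(regions)),
    stringsAsFactors = FALSE)

  perturb <- function(resid) {
    pos <- resid > 0
    if (sum(pos) <= 1L) return(resid)
    g <- stats::rgamma(sum(pos), shape = config$region_concentration * resid[pos])
    if (sum(g) <= 0) return(resid)
    resid[pos] <- g / sum(g)
    resid
  }

  mut_ids <- unlist(lapply(ids, function(cl)
    sprintf("%s_m%02d", cl, seq_len(n_mut[[cl]]))), use.names = FALSE)
  cluster_of <- rep(ids, times = n_mut[ids])

  rows <- list()
  for (l in names(regions)) {
    for (s in regions[[l]]) {
      resid_s <- if (length(regions[[l]]) > 1L && config$noise != "none")
                   perturb(truth$composition[[l]])
                 else truth$composition[[l]]
      ccf_s <- .resid_to_ccf(resid_s, parent)
      true_ccf <- ccf_s[cluster_of]
      if (config$noise == "binomial") {
        vaf <- pmin(pmax(config$purity * true_ccf / 2, 0), 1)
        alt <- stats::rbinom(length(true_ccf), config$depth, vaf)
        obs <- ccf_from_counts(alt, config$depth - alt, config$purity, 2, 1)
        rows[[s]] <- data.frame(mutation_id = mut_ids, sample_id = s,
                                ccf = obs, depth = config$depth,
                                cluster_id = cluster_of,
                                alt_count = alt,
                                ref_count = config$depth - alt,
                                stringsAsFactors = FALSE)
      } else {
        rows[[s]] <- data.frame(mutation_id = mut_ids, sample_id = s,
                                ccf = unname(true_ccf), depth = config$depth,
                                cluster_id = cluster_of,
                                stringsAsFactors = FALSE)
      }
    }
  }
  mutations <- do.call(rbind, rows)
  rownames(mutations) <- NULL
  patient_dataset("SIM", mutations, truth$lesions, region_df)
}

#' Simulate a full synthetic patient
#'
#' Convenience wrapper: clone tree, seeding history, observations.
#'
#' @param config A [simulation_config()].
#' @param seed Optional integer seed (applied via [set.seed()]).
#' @return List with `dataset` (a [patient_dataset()]) and `truth`
#'   (a `"ground_truth"`).
#' @export
simulate_patient <- function(config = simulation_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- simulate_clone_tree(config)
  truth <- simulate_metastatic_history(tree, config)
  dataset <- simulate_observations(truth, config)
  list(dataset = dataset, truth = truth)
}

#' Score an inferred map and tree against the ground truth
#'
#' Route recovery is scored over (source, target) pairs; a route whose
#' target sits in an inferred ambiguity group counts as correct when the
#' true source lies among the group's admissible orderings (another group
#' member or the group's external source). Since both the truth and the
#' inference carry exactly one route per metastasis, precision and recall
#' coincide. Seeding-class accuracy compares the per-metastasis
#' monoclonal/multiclonal call; parent accuracy compares parent assignments
#' over the clusters shared by both trees.
#'
#' @param map A `metastatic_map`.
#' @param tree The inferred `clone_tree` (or `NULL` to skip tree scoring).
#' @param truth A `"ground_truth"`.
#' @return List: `route_precision`, `route_recall`, `route_f1`,
#'   `class_accuracy`, `parent_accuracy`, `n_routes`.
#' @export
evaluate_recovery <- function(map, tree, truth) {
  stopifnot(inherits(map, "metastatic_map"), inherits(truth, "ground_truth"))
  tr <- truth$routes
  mets <- tr$target_lesion
  if (!all(mets %in% c(map$routes$target_lesion, map$lesions$lesion_id)))
    stop("evaluate_recovery: lesion universes differ")
  inferred <- stats::setNames(map$routes$source_lesion, map$routes$target_lesion)
  groups <- map$ambiguity_groups
  group_external <- lapply(groups, function(g) {
    src <- inferred[g]
    unname(src[!(src %in% g)])
  })
  correct <- vapply(seq_along(mets), function(i) {
    m <- mets[i]; ts <- tr$source_lesion[i]
    if (!m %in% names(inferred)) return(FALSE)
    if (identical(unname(inferred[[m]]), ts)) return(TRUE)
    for (j in seq_along(groups)) {
      g <- groups[[j]]
      if (m %in% g && (ts %in% setdiff(g, m) || ts %in% group_external[[j]]))
        return(TRUE)
    }
    FALSE
  }, logical(1))
  n_true <- length(mets)
  n_inf <- nrow(map$routes)
  precision <- if (n_inf == 0) 0 else sum(correct) / n_inf
  recall <- if (n_true == 0) 0 else sum(correct) / n_true
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)

  inferred_class <- stats::setNames(map$routes$seeding_class,
                                    map$routes$target_lesion)
  cls_ok <- vapply(seq_along(mets), function(i) {
    m <- mets[i]
    m %in% names(inferred_class) &&
      identical(unname(inferred_class[[m]]), tr$seeding_class[i])
  }, logical(1))

  parent_accuracy <- NA_real_
  if (!is.null(tree)) {
    shared <- intersect(names(tree$parent), names(truth$tree$parent))
    shared <- setdiff(shared, c(tree$root, truth$tree$root))
    if (length(shared))
      parent_accuracy <- mean(vapply(shared, function(n)
        identical(tree$parent[[n]], truth$tree$parent[[n]]), logical(1)))
  }
  list(route_precision = precision, route_recall = recall, route_f1 = f1,
       class_accuracy = mean(cls_ok), parent_accuracy = parent_accuracy,
       n_routes = n_true)
}
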