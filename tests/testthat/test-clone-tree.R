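test_that("cluster roles: trunk is the unique all-clonal cluster", {
  st <- status_matrix(
    tr = rep("clonal", 4),
    br = c("clonal", "subclonal", "clonal", "clonal"),   # everywhere, not all clonal
    b2 = c("subclonal", "subclonal", "absent", "absent"),
    lf = c("absent", "absent", "subclonal", "absent"))
  colnames(st) <- paste0("L", 1:4)
  roles <- classify_cluster_roles(st)
  expect_equal(roles$role[roles$cluster_id == "tr"], "trunk")
  expect_equal(roles$role[roles$cluster_id == "br"], "branch")
  expect_equal(roles$role[roles$cluster_id == "b2"], "branch")
  expect_equal(roles$role[roles$cluster_id == "lf"], "leaf")

  two_trunks <- status_matrix(a = rep("clonal", 2), b = rep("clonal", 2))
  colnames(two_trunks) <- c("L1", "L2")
  expect_error(classify_cluster_roles(two_trunks), "ambiguous MRCA")

  no_trunk <- status_matrix(a = c("clonal", "subclonal"),
                            b = c("subclonal", "clonal"))
  colnames(no_trunk) <- c("L1", "L2")
  expect_error(classify_cluster_roles(no_trunk), "no trunk")
})

test_that("pairwise relations implement the linear/branching rules", {
  expect_equal(pairwise_relation(c(0.9, 0.8), c(0.4, 0.3)), "linear_a_over_b")
  expect_equal(pairwise_relation(c(0.4, 0.3), c(0.9, 0.8)), "linear_b_over_a")
  expect_equal(pairwise_relation(c(0.6, 0.2), c(0.3, 0.5)), "branching")
  # equal CCFs summing above one force a linear relationship
  expect_equal(pairwise_relation(0.6, 0.6), "linear_a_over_b")
  # equal profiles with low sums leave the pair undetermined
  expect_equal(pairwise_relation(c(0.3, 0.3), c(0.3, 0.3)), "undetermined")
  # a reversal beats the sum condition (branching wins)
  expect_equal(pairwise_relation(c(0.9, 0.1), c(0.2, 0.8)), "branching")
})

test_that("pairwise relations mirror under argument swap", {
  set.seed(11)
  mirror <- c(linear_a_over_b = "linear_b_over_a",
              linear_b_over_a = "linear_a_over_b",
              branching = "branching", undetermined = "undetermined")
  for (i in 1:200) {
    a <- round(runif(3), 2); b <- round(runif(3), 2)
    if (all(a == b)) next  # orientation of exact ties is conventional
    expect_equal(pairwise_relation(b, a),
                 unname(mirror[pairwise_relation(a, b)]))
  }
})

test_that("a pure chain of CCFs reconstructs as a chain (oracle-checked)", {
  ccf <- matrix(rep(c(1.0, 0.8, 0.45), 2), nrow = 3,
                dimnames = list(c("k1", "k2", "k3"), c("L1", "L2")))
  valid <- oracle_valid_trees(ccf)
  expect_length(valid, 1L)  # enumeration leaves exactly one tree
  expect_equal(valid[[1]][c("k2", "k3")], c(k2 = "k1", k3 = "k2"))

  mat <- cluster_ccf_matrix(ccf)
  st <- call_clonality(mat)
  tree <- build_clone_tree(mat, st, classify_cluster_roles(st))
  expect_equal(tree$parent[c("k2", "k3")], c(k2 = "k1", k3 = "k2"))
})

test_that("sister lineages cannot both nest under an ancestor they jointly exceed", {
  # B and C are branching (reversed between lesions); B + C exceeds A in L1,
  # so at least one of them must attach above A
  ccf <- rbind(tr = c(1.00, 1.00),
               A  = c(0.55, 0.55),
               B  = c(0.45, 0.10),
               C  = c(0.30, 0.45))
  colnames(ccf) <- c("L1", "L2")
  mat <- cluster_ccf_matrix(ccf)
  st <- call_clonality(mat)
  tree <- build_clone_tree(mat, st, classify_cluster_roles(st))
  under_A <- vapply(c("B", "C"), function(n)
    "A" %in% oracle_ancestors(tree$parent, n), logical(1))
  expect_false(all(under_A))
  # and the oracle agrees no valid tree has both under A
  for (tr in oracle_valid_trees(ccf)) {
    both <- all(vapply(c("B", "C"), function(n)
      "A" %in% oracle_ancestors(tr, n), logical(1)))
    expect_false(both)
  }
})

test_that("inconsistent CCF matrices fail loudly", {
  # x and y reverse between lesions (branching) yet sum far above 1,
  # which would force nesting: no tree can satisfy both
  ccf <- rbind(tr = c(1.0, 1.0), x = c(0.95, 0.30), y = c(0.30, 0.95))
  colnames(ccf) <- c("L1", "L2")
  mat <- cluster_ccf_matrix(ccf)
  st <- call_clonality(mat)
  expect_error(build_clone_tree(mat, st, classify_cluster_roles(st)),
               "pigeonhole")
})

test_that("the worked Patient_8 example yields the narrative tree deterministically", {
  res <- analyze_patient(example_patient8())
  expected <- c(c2 = "c1", c3 = "c2", c4 = "c3", c5 = "c4", c6 = "c3",
                c7 = "c2")
  expect_equal(res$tree$parent[names(expected)], expected)
  expect_equal(res$tree$roles[["c8"]], "leaf")
  expect_equal(res$tree$parent[["c8"]], "c2")  # deepest clonal cluster in P5
  # determinism across repeated runs
  res2 <- analyze_patient(example_patient8())
  expect_identical(res$tree$parent, res2$tree$parent)
})

test_that("nested ovals report containment and flag impossible lesions", {
  tree <- make_tree(c(a = NA_character_, b = "a", c = "b"))
  ccf <- rbind(a = c(1.0, 1.0), b = c(1.0, 0.0), c = c(0.4, 0.3))
  colnames(ccf) <- c("L1", "L2")
  mat <- cluster_ccf_matrix(ccf)
  st <- call_clonality(mat)
  # L1: chain a > b > c
  ov <- nested_ovals(tree, st[, "L1", drop = FALSE], mat)
  expect_equal(ov$L1$cluster_id, c("a", "b", "c"))
  expect_equal(ov$L1$depth, 0:2)
  # L2: c present but its parent b absent -> violation
  expect_error(nested_ovals(tree, st, mat), "parent b is absent")
  ov2 <- nested_ovals(tree, st, mat, strict = FALSE)
  expect_length(attr(ov2$L2, "violations"), 1L)
})

test_that("pigeonhole search agrees with exhaustive enumeration on random instances", {
  set.seed(301)
  n_unique <- 0L
  for (i in 1:150) {
    inst <- random_ccf_instance(sample(3:5, 1), sample(2:4, 1),
                                jitter = sample(c(0, 0.02), 1))
    valid <- oracle_valid_trees(inst$ccf)
    mat <- cluster_ccf_matrix(inst$ccf)
    st <- call_clonality(mat)
    roles <- tryCatch(classify_cluster_roles(st), error = function(e) NULL)
    if (is.null(roles)) next
    built <- tryCatch(build_clone_tree(mat, st, roles), error = function(e) NULL)
    if (length(valid) == 0L) {
      expect_null(built)
    } else {
      expect_false(is.null(built))
      matches <- vapply(valid, function(v)
        identical(v[names(built$parent)], built$parent), logical(1))
      expect_true(any(matches))  # always among the survivors
      if (length(valid) == 1L) n_unique <- n_unique + 1L
    }
  }
  expect_gt(n_unique, 20L)  # the family genuinely exercises unique cases
})
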