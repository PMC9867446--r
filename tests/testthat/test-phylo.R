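model <- jtt_model()

test_that("the JTT rate matrix is a proper reversible generator", {
  Q <- model$Q
  expect_equal(rowSums(Q), rep(0, 20), tolerance = 1e-12,
               ignore_attr = TRUE)
  # detailed balance pi_i Q_ij = pi_j Q_ji
  F <- diag(model$pi) %*% Q
  expect_equal(F, t(F), tolerance = 1e-12, ignore_attr = TRUE)
  # unit expected substitution rate
  expect_equal(-sum(model$pi * diag(Q)), 1, tolerance = 1e-12)
})

test_that("P(t) is stochastic, P(0) = I, Chapman-Kolmogorov holds", {
  expect_equal(jtt_transition_matrix(model, 0), diag(20),
               tolerance = 1e-10, ignore_attr = TRUE)
  for (t in c(0.01, 0.1, 1, 10)) {
    P <- jtt_transition_matrix(model, t)
    expect_true(all(P >= 0))
    expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  expect_equal(jtt_transition_matrix(model, 0.2) %*%
                 jtt_transition_matrix(model, 0.5),
               jtt_transition_matrix(model, 0.7),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(jtt_transition_matrix(model, -1), "nonnegative")
})

test_that("ML distances: zero for identical inputs, symmetric, recovers t", {
  s <- random_protein(200)
  expect_equal(ml_pairwise_distance(s, s, model), 0)
  tree <- ape::read.tree(text = "(A:0.15,B:0.15);")
  root <- withr::with_seed(53, random_protein(10000))
  leaves <- simulate_evolution(root, tree, model, seed = 54)
  d <- ml_pairwise_distance(leaves[["A"]], leaves[["B"]], model)
  expect_equal(d, 0.3, tolerance = 0.03 / 0.3)  # within ±0.03 absolute
  expect_equal(ml_pairwise_distance(leaves[["B"]], leaves[["A"]], model), d,
               tolerance = 1e-6)
  expect_error(ml_pairwise_distance("A-", "-A", model), "no shared")
})

test_that("neighbor joining: 3-taxon closed form and additive recovery", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- build_nj_tree(d)
  # closed-form 3-point branch lengths: (dab+dac-dbc)/2 etc.
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl["a"]), (5 + 9 - 10) / 2)
  expect_equal(unname(bl["b"]), (5 + 10 - 9) / 2)
  expect_equal(unname(bl["c"]), (9 + 10 - 5) / 2)
  # exact topology recovery from an additive 8-leaf matrix
  true <- withr::with_seed(59, ape::rtree(8))
  D <- additive_matrix(true)
  expect_true(same_topology(build_nj_tree(D), true))
  # label-order invariance of the unrooted topology
  perm <- sample(8)
  expect_true(same_topology(build_nj_tree(D[perm, perm]), true))
  expect_error(build_nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("pruning equals the closed form on a 2-leaf, 1-site toy", {
  tree <- ape::read.tree(text = "(x:0.2,y:0.4);")
  aln <- c(x = "A", y = "R")
  Pa <- jtt_transition_matrix(model, 0.2)
  Pb <- jtt_transition_matrix(model, 0.4)
  hand <- log(sum(model$pi * Pa[, "A"] * Pb[, "R"]))
  expect_equal(tree_log_likelihood(tree, aln, model), hand,
               tolerance = 1e-10)
})

test_that("pruning equals exhaustive state enumeration on 4-leaf toys", {
  trees <- c("((A:0.1,B:0.3):0.2,C:0.15,D:0.4);",
             "((A:0.5,C:0.1):0.05,B:0.2,D:0.3);")
  withr::with_seed(61, {
    for (txt in trees) {
      tree <- ape::read.tree(text = txt)
      aln <- setNames(vapply(1:4, function(i) random_protein(2),
                             character(1)), tree$tip.label)
      expect_equal(tree_log_likelihood(tree, aln, model),
                   loglik_enumeration_oracle(tree, aln, model),
                   tolerance = 1e-8)
    }
  })
})

test_that("likelihood is invariant to root placement (pulley principle)", {
  tree <- ape::read.tree(text = "((A:0.1,B:0.3):0.2,(C:0.15,D:0.4):0.1);")
  aln <- withr::with_seed(67, setNames(
    vapply(1:4, function(i) random_protein(30), character(1)),
    tree$tip.label))
  ll_rooted <- tree_log_likelihood(tree, aln, model)
  ll_unrooted <- tree_log_likelihood(ape::unroot(tree), aln, model)
  expect_equal(ll_rooted, ll_unrooted, tolerance = 1e-8)
})

test_that("NNI search keeps the truth and fixes a one-move error", {
  true <- ape::read.tree(
    text = "((A:0.1,B:0.1):0.25,(C:0.1,D:0.1):0.25,E:0.3);")
  root <- withr::with_seed(71, random_protein(300))
  aln <- simulate_evolution(root, true, model, seed = 72)
  start <- build_nj_tree(ml_distance_matrix(aln, model))
  expect_true(same_topology(start, true))  # NJ already recovers this one
  res <- nni_search(start, aln, model, max_rounds = 3)
  expect_true(same_topology(res$tree, true))
  expect_equal(res$rounds, 0L)  # truth is a local optimum: no move accepted
  # start one NNI away: swap B and C
  wrong <- ape::read.tree(
    text = "((A:0.1,C:0.1):0.25,(B:0.1,D:0.1):0.25,E:0.3);")
  ll_wrong <- tree_log_likelihood(wrong, aln, model)
  res <- nni_search(wrong, aln, model, max_rounds = 3)
  expect_true(same_topology(res$tree, true))
  expect_gt(res$loglik, ll_wrong)  # accepted moves only increase loglik
})

test_that("bootstrap supports are reproducible percentages in [0, 100]", {
  true <- ape::read.tree(
    text = "((A:0.05,B:0.05):1.0,(C:0.05,D:0.05):1.0,E:0.6);")
  root <- withr::with_seed(73, random_protein(300))
  aln <- simulate_evolution(root, true, model, seed = 74)
  bs1 <- bootstrap_support(aln, model, replicates = 25, seed = 75)
  bs2 <- bootstrap_support(aln, model, replicates = 25, seed = 75)
  expect_identical(ape::write.tree(bs1$tree), ape::write.tree(bs2$tree))
  sup <- as.numeric(bs1$tree$node.label)
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_error(bootstrap_support(aln, model, replicates = 25), "seed")
})

test_that("subgroup assignment splits taxa by the anchor clades", {
  tree <- ape::read.tree(text = paste0(
    "(((AtCLCa:1,Q1:1):1,(AtCLCd:1,Q2:1):1):2,",
    "((AtCLCe:1,Q3:1):1,AtCLCf:1):2);"))
  call <- assign_subgroup(tree, c("AtCLCa", "AtCLCd"),
                          c("AtCLCe", "AtCLCf"))
  expect_equal(unname(call[c("Q1", "Q2", "Q3")]), c("I", "I", "II"))
  expect_equal(sort(unique(call)), c("I", "II"))
  expect_error(assign_subgroup(tree, c("AtCLCa"), character(0)),
               "non-empty")
  expect_error(assign_subgroup(tree, c("AtCLCa"), c("NOPE")), "not in tree")
  # interleaved anchors: no separating split
  inter <- ape::read.tree(
    text = "((AtCLCa:1,AtCLCe:1):1,(AtCLCd:1,AtCLCf:1):1);")
  expect_error(assign_subgroup(inter, c("AtCLCa", "AtCLCd"),
                               c("AtCLCe", "AtCLCf")), "interleaved")
})

test_that("newick round-trips through files with node labels", {
  tree <- ape::read.tree(text = "((A:1,B:2)90:0.5,(C:1,D:1)75:0.4);")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, f)
  back <- read_newick(f)
  expect_equal(back$tip.label, tree$tip.label)
  expect_equal(back$node.label, tree$node.label)
  expect_equal(back$edge.length, tree$edge.length)
})
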