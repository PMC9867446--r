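test_that("generation is a pure function of (blueprint, seed)", {
  bp <- clc_blueprint(seed = 101L)
  g1 <- generate_clc_protein(bp)
  g2 <- generate_clc_protein(bp)
  expect_identical(g1$record$sequence, g2$record$sequence)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_clc_protein(clc_blueprint(seed = 102L))
  expect_false(identical(g1$record$sequence, g3$record$sequence))
})

test_that("planted motifs are recovered exactly at their coordinates", {
  for (s in c(1L, 2L, 3L)) {
    g <- generate_clc_protein(clc_blueprint(seed = s))
    tru <- g$truth
    seq <- g$record$sequence
    for (nm in c("GxGxPE", "GKxGPxxH", "PxxGxLF")) {
      hits <- scan_motif(seq, clc_motifs()[[nm]])
      expect_equal(hits$start, tru$start[tru$feature == nm],
                   info = paste(nm, "seed", s))
    }
    # sorting signals: exactly the planted ones inside the windows
    sig <- find_sorting_signals(seq, n_limit = 120)
    planted <- tru[startsWith(tru$feature, "signal_"), ]
    expect_equal(sort(sig$start), sort(planted$start))
    expect_equal(nrow(sig), nrow(planted))
  }
})

test_that("ground truth drives exact downstream recovery", {
  g <- generate_clc_protein(clc_blueprint(filter_residue2 = "P", seed = 4L))
  a <- annotate_protein(g$record$sequence, "gt", reference_bundle())
  tru <- g$truth
  expect_equal(a$selectivity$filter_start,
               tru$start[tru$feature == "GxGxPE"])
  expect_equal(a$glutamates$gating$position,
               tru$start[tru$feature == "gating_glutamate"])
  expect_equal(a$glutamates$proton$position,
               tru$start[tru$feature == "proton_glutamate"])
  cbs1 <- tru[tru$feature == "CBS1", ]
  hit <- a$cbs[a$cbs$domain == "CBS1", ]
  expect_equal(hit$start, cbs1$start)
  expect_equal(hit$end, cbs1$end)
})

test_that("blueprint validation rejects impossible architectures", {
  expect_error(clc_blueprint(filter_residue2 = "Q"), "must be")
  expect_error(clc_blueprint(tm_count = 3L), "at least 5")
  expect_error(clc_blueprint(linker_len = 6L), ">= 10")
  expect_error(clc_blueprint(c_term_len = 50L), "too short")
})

test_that("reverse translation round-trips and is seed-deterministic", {
  withr::with_seed(83, {
    for (i in 1:10) {
      p <- random_protein(sample(20:80, 1))
      cds <- reverse_translate(p, seed = i)
      expect_equal(translate_cds(cds), p)
    }
  })
  p <- random_protein(50)
  expect_identical(reverse_translate(p, seed = 7),
                   reverse_translate(p, seed = 7))
  expect_false(identical(reverse_translate(p, seed = 7),
                         reverse_translate(p, seed = 8)))
})

test_that("evolution simulation: zero branches copy, P(t) rows verified", {
  model <- jtt_model()
  tree <- ape::read.tree(text = "(A:0,B:0);")
  root <- withr::with_seed(89, random_protein(120))
  leaves <- simulate_evolution(root, tree, model, seed = 90)
  expect_equal(unname(leaves[["A"]]), root)
  expect_equal(unname(leaves[["B"]]), root)
  # substitution frequencies from a leucine root match P(0.1)["L", ]
  tree <- ape::read.tree(text = "(A:0.1,B:0);")
  root <- strrep("L", 20000)
  leaves <- simulate_evolution(root, tree, model, seed = 91)
  obs <- table(factor(strsplit(leaves[["A"]], "")[[1]],
                      levels = clcscan:::AA_PAML))
  expected <- jtt_transition_matrix(model, 0.1)["L", ] * 20000
  # chi-square goodness of fit against the model row
  chi <- sum((obs - expected)^2 / pmax(expected, 1e-9))
  expect_lt(chi, qchisq(0.999, df = 19))
  # determinism
  l2 <- simulate_evolution(root, tree, model, seed = 91)
  expect_identical(leaves, l2)
})

test_that("pairwise ML distances track simulated path lengths", {
  model <- jtt_model()
  tree <- ape::read.tree(
    text = "((A:0.1,B:0.2):0.1,(C:0.15,D:0.05):0.1);")
  root <- withr::with_seed(97, random_protein(5000))
  leaves <- simulate_evolution(root, tree, model, seed = 98)
  D <- ml_distance_matrix(leaves, model)
  path <- additive_matrix(tree)
  expect_equal(D[rownames(path), colnames(path)], path, tolerance = 0.12)
})
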