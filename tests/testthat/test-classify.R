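refs <- reference_bundle()

test_that("selectivity filter extraction: motif path and residue-2 call", {
  s <- paste0(strrep("A", 30), "GPGIPE", strrep("A", 30))
  call <- extract_selectivity_filter(s)
  expect_equal(call$specificity, "nitrate")
  expect_equal(call$residue2, "P")
  expect_equal(call$filter_display, "GPGIP")
  expect_equal(call$filter_start, 31L)
  call <- extract_selectivity_filter(gsub("GPGIPE", "GSGIPE", s))
  expect_equal(call$specificity, "chloride")
  expect_equal(call$filter_display, "GSGIP")
})

test_that("degenerate filters are recovered through the anchor fallback", {
  g <- generate_clc_protein(clc_blueprint(filter_residue2 = NA, seed = 14L),
                            "deg")
  call <- extract_selectivity_filter(g$record$sequence, refs$reference,
                                     refs$filter_start, refs$filter_len)
  expect_equal(call$specificity, "degenerate")
  expect_equal(call$filter_seq, "SSKSSQ")
  # no reference: unknown
  call <- extract_selectivity_filter(strrep("A", 50))
  expect_equal(call$specificity, "unknown")
})

test_that("glutamate anchors map in query numbering; only E counts", {
  g <- generate_clc_protein(clc_blueprint(seed = 15L), "q")
  st <- glutamate_status(g$record$sequence, refs$reference, refs$anchors)
  tru <- g$truth
  expect_true(st$gating$present)
  expect_true(st$proton$present)
  expect_equal(st$gating$position,
               tru$start[tru$feature == "gating_glutamate"])
  expect_equal(st$proton$position,
               tru$start[tru$feature == "proton_glutamate"])
  # identity mapping on the reference itself
  st <- glutamate_status(refs$reference, refs$reference, refs$anchors)
  expect_equal(st$gating$position, unname(refs$anchors["gating"]))
  # D (aspartate) does not count as present
  q <- refs$reference
  substr(q, refs$anchors[["gating"]], refs$anchors[["gating"]]) <- "D"
  st <- glutamate_status(q, refs$reference, refs$anchors)
  expect_false(st$gating$present)
  expect_equal(st$gating$residue, "D")
})

test_that("the two-glutamate decision table is total", {
  mk <- function(g, p) list(gating = list(present = g),
                            proton = list(present = p))
  expect_equal(call_transport_mechanism(mk(TRUE, TRUE))$mechanism,
               "antiporter")
  expect_equal(call_transport_mechanism(mk(TRUE, FALSE))$mechanism, "channel")
  expect_equal(call_transport_mechanism(mk(FALSE, TRUE))$mechanism, "channel")
  expect_equal(call_transport_mechanism(mk(FALSE, FALSE))$mechanism,
               "unknown")
  # function composition marks non-antiporter calls low confidence
  expect_equal(function_call("nitrate", "antiporter")$call,
               "NO3-/H+ exchange")
  expect_false(function_call("nitrate", "antiporter")$low_confidence)
  expect_true(function_call("chloride", "channel")$low_confidence)
})

test_that("CBS domains: planted copy found, shuffles rejected, 20% noise kept", {
  cbs <- clcscan:::synthetic_cbs_segments()
  base <- generate_clc_protein(clc_blueprint(cbs_copies = 0L, seed = 16L),
                               "nocbs")$record$sequence
  # no CBS planted: nothing found
  expect_equal(nrow(locate_cbs_domains(base, refs$cbs)), 0L)
  # verbatim copy appended in the C-terminal half: identity 100
  with_cbs <- paste0(base, cbs[["CBS1"]])
  hit <- locate_cbs_domains(with_cbs, refs$cbs["CBS1"])
  expect_equal(hit$domain, "CBS1")
  expect_equal(hit$identity, 100)
  expect_equal(substr(with_cbs, hit$start, hit$end), cbs[["CBS1"]])
  # shuffled segments (same composition) never qualify
  withr::with_seed(17, {
    for (i in 1:15) {
      shuf <- paste(sample(strsplit(cbs[["CBS1"]], "")[[1]]), collapse = "")
      expect_equal(nrow(locate_cbs_domains(paste0(base, shuf),
                                           refs$cbs["CBS1"])), 0L)
    }
    # 20% substitution noise keeps the hit
    ch <- strsplit(cbs[["CBS1"]], "")[[1]]
    idx <- sample(50, 10)
    ch[idx] <- sample(AA20, 10, replace = TRUE)
    noisy <- paste0(base, paste(ch, collapse = ""))
    expect_equal(nrow(locate_cbs_domains(noisy, refs$cbs["CBS1"])), 1L)
  })
})

test_that("annotate_protein assembles consistent reports and never aborts", {
  g <- generate_clc_protein(clc_blueprint(filter_residue2 = "P", seed = 18L),
                            "anno")
  a <- annotate_protein(g$record$sequence, "anno", refs)
  expect_s3_class(a, "clc_annotation")
  expect_equal(a$selectivity$specificity, "nitrate")
  expect_equal(a$mechanism$mechanism, "antiporter")
  expect_equal(a$function_call$call, "NO3-/H+ exchange")
  expect_equal(a$tm_count, 12L)
  expect_setequal(a$cbs$domain, c("CBS1", "CBS2"))
  expect_true(all(c("N", "C") %in% a$sorting_signals$terminus))
  # an all-X record degrades to not-determined fields instead of aborting
  a <- annotate_protein(strrep("X", 40), "bad", refs)
  expect_equal(a$mass_kda$reason,
               "compute_mass: unknown residue 'X' at position 1")
  expect_equal(a$function_call$call, "not determined")
  tab <- report_table(list(a))
  expect_equal(tab$mass_kda, "not determined")
})

test_that("reports render to the fixed TSV column set", {
  g1 <- generate_clc_protein(clc_blueprint(seed = 19L), "r1")
  g2 <- generate_clc_protein(clc_blueprint(filter_residue2 = "S",
                                           proton_glutamate = FALSE,
                                           seed = 20L), "r2")
  reports <- list(annotate_protein(g1$record$sequence, "r1", refs),
                  annotate_protein(g2$record$sequence, "r2", refs))
  tab <- report_table(reports)
  expect_equal(tab$id, c("r1", "r2"))
  expect_equal(names(tab),
               c("id", "length", "mass_kda", "pI", "gravy", "best_homolog",
                 "func", "filter", "Eg", "Ep", "tm_count", "cbs",
                 "n_signals"))
  expect_equal(tab$Ep, c("E", "T"))
  expect_equal(tab$func, c("NO3-/H+ exchange", "Cl- channel?"))
})
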