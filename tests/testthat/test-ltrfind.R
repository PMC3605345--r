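# LTR-pair detection, TSD validation, boundary polishing.

test_that("random sequence yields no candidates", {
  g <- local({ set.seed(77); random_dna(50000) })
  expect_equal(nrow(find_ltr_pairs(c(rand = g))), 0)
})

test_that("a single implanted element is recovered within +/-5 nt", {
  gen <- generate_genome(list(bg_length = 20000, insertions = list(
    insertion_spec(clade_template("Reina", ltr_length = 500), 5000,
                   ltr_divergence = 0.02))), seed = 11)
  cands <- find_ltr_pairs(gen$genome)
  expect_equal(nrow(cands), 1)
  tr <- gen$truth[1, ]
  expect_lte(max(abs(c(cands$ltr5_start - tr$ltr5_start,
                       cands$ltr5_end - tr$ltr5_end,
                       cands$ltr3_start - tr$ltr3_start,
                       cands$ltr3_end - tr$ltr3_end))), 5)
})

test_that("identical 631-nt LTRs with 4776-nt internal region span 6038 nt", {
  gen <- generate_genome(list(bg_length = 20000, insertions = list(
    insertion_spec(clade_template("Galadriel", ltr_length = 631,
                                  internal_length = 4776), 5000))), seed = 3)
  g <- gen$genome[[1]]
  cands <- find_ltr_pairs(gen$genome)
  expect_equal(nrow(cands), 1)
  cand <- refine_boundaries(g, as.list(cands[1, ]))
  expect_equal(cand$ltr3_end - cand$ltr5_start, 6038)
  expect_equal(cand$ltr_identity, 1.0)
})

test_that("detect_tsd follows the mismatch budget and flags edges", {
  elem <- strrep("ACGT", 25)
  g <- paste0("TTTTTTTTTT", "GTAGG", elem, "GTAGG", "TTTTTTTTTT")
  cand <- list(ltr5_start = 15L, ltr3_end = 15L + nchar(elem))
  call <- detect_tsd(g, cand)
  expect_true(call$present)
  expect_equal(call$tsd_sequence, "GTAGG")
  expect_equal(call$length, 5L)

  g2 <- paste0("TTTTTTTTTT", "AAAAA", elem, "AAAAT", "TTTTTTTTTT")
  expect_false(detect_tsd(g2, cand)$present)
  call2 <- detect_tsd(g2, cand, max_mismatch = 1)
  expect_true(call2$present)
  expect_equal(call2$mismatches, 1L)

  edge <- detect_tsd(paste0("AG", elem, "AG"),
                     list(ltr5_start = 2L, ltr3_end = 2L + nchar(elem)))
  expect_false(edge$present)
  expect_true(edge$edge)
})

test_that("refine_boundaries recovers offset boundaries and is idempotent", {
  sim <- fixture_sim()
  g <- sim$genome[[1]]
  tr <- sim$truth[2, ]
  # candidate displaced +3 from the perfect TSD configuration
  cand <- list(seq_id = tr$seq_id,
               ltr5_start = tr$ltr5_start + 3L, ltr5_end = tr$ltr5_end + 3L,
               ltr3_start = tr$ltr3_start + 3L, ltr3_end = tr$ltr3_end + 3L,
               ltr_identity = NA_real_, strand = "+", partial = FALSE,
               tsd_refined = FALSE)
  ref1 <- refine_boundaries(g, cand)
  expect_equal(ref1$ltr5_start, tr$ltr5_start)
  expect_equal(ref1$ltr3_end, tr$ltr3_end)
  expect_true(ref1$tsd_refined)
  ref2 <- refine_boundaries(g, ref1)
  expect_equal(ref2[c("ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end")],
               ref1[c("ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end")])
})

test_that("candidates are unique, sorted, and strand-symmetric", {
  sim <- fixture_sim()
  cands <- find_ltr_pairs(sim$genome)
  expect_equal(nrow(cands), nrow(sim$truth))
  expect_false(is.unsorted(cands$ltr5_start))
  spans <- cbind(cands$ltr5_start, cands$ltr3_end)
  expect_true(all(spans[-1, 1] >= spans[-nrow(spans), 2]))
  # mirrored candidate set on the reverse complement
  n <- nchar(sim$genome[[1]])
  rc <- c(rc = revcomp(sim$genome[[1]]))
  rcands <- find_ltr_pairs(rc)
  expect_equal(nrow(rcands), nrow(cands))
  expect_equal(sort(n - rcands$ltr3_end), sort(cands$ltr5_start), tolerance = 0,
               ignore_attr = TRUE)
})

test_that("degenerate parameters raise a config error", {
  expect_error(find_ltr_pairs(c(a = strrep("ACGT", 2000)),
                              list(min_ltr = 500, max_ltr = 100)),
               class = "chromoscan_config_error")
  expect_error(find_ltr_pairs(c(a = strrep("ACGT", 2000)), list(k = 4)),
               class = "chromoscan_config_error")
})
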