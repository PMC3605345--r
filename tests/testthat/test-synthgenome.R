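# Generator: determinism, truth-channel fidelity, divergence calibration.

test_that("empty config gives background-only genome and empty truth", {
  gen <- generate_genome(list(bg_length = 5000), seed = 1)
  expect_equal(nchar(gen$genome[[1]]), 5000)
  expect_equal(nrow(gen$truth), 0)
})

test_that("identical (config, seed) runs are byte-identical", {
  cfg <- list(bg_length = 20000, insertions = list(
    insertion_spec(clade_template("Reina"), 2000, ltr_divergence = 0.02),
    insertion_spec(clade_template("CRM"), 12000, ltr_divergence = 0.01)))
  a <- generate_genome(cfg, seed = 42)
  b <- generate_genome(cfg, seed = 42)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth, b$truth)
  c <- generate_genome(cfg, seed = 43)
  expect_false(identical(a$genome, c$genome))
})

test_that("realized LTR divergence is an unbiased binomial draw", {
  tpl <- clade_template("Reina", ltr_length = 450)
  specs <- lapply(seq_len(50), function(i)
    insertion_spec(tpl, i * 600L, ltr_divergence = 0.02))
  gen <- generate_genome(list(bg_length = 300000, insertions = specs,
                              min_spacing = 100), seed = 9)
  realized <- gen$truth$realized_divergence
  se <- sqrt(0.02 * 0.98 / 450)
  expect_lt(abs(mean(realized) - 0.02), 3 * se / sqrt(50))
  # binomial test on the pooled mutation count at alpha = 0.01
  pooled <- stats::binom.test(round(sum(realized) * 450), 450 * 50, p = 0.02)
  expect_gt(pooled$p.value, 0.01)
})

test_that("truth features are re-locatable and TSD copies identical", {
  sim <- fixture_sim()
  g <- sim$genome[[1]]
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    left <- substr(g, tr$tsd_left_start + 1, tr$tsd_left_start + nchar(tr$tsd))
    right <- substr(g, tr$tsd_right_start + 1, tr$tsd_right_start + nchar(tr$tsd))
    expect_identical(left, tr$tsd)
    expect_identical(right, tr$tsd)
    # LTR copies differ only at divergence sites
    l5 <- substr(g, tr$ltr5_start + 1, tr$ltr5_end)
    l3 <- substr(g, tr$ltr3_start + 1, tr$ltr3_end)
    expect_equal(realized_divergence(l5, l3), tr$realized_divergence)
    # features nest within the element span
    expect_true(tr$start <= tr$ltr5_start && tr$ltr3_end <= tr$end)
    expect_true(tr$pbs_start >= tr$start && tr$pbs_end <= tr$end)
  }
})

test_that("reverse-orientation insertion is the reverse complement of forward", {
  tpl <- clade_template("Galadriel")
  mk <- function(orient) generate_genome(list(
    bg_length = 10000,
    insertions = list(insertion_spec(tpl, 2000, ltr_divergence = 0.03,
                                     orientation = orient))), seed = 5)
  fw <- mk("forward"); rv <- mk("reverse")
  ef <- substr(fw$genome[[1]], fw$truth$start + 1, fw$truth$end)
  er <- substr(rv$genome[[1]], rv$truth$start + 1, rv$truth$end)
  expect_identical(er, revcomp(ef))
})

test_that("placement and configuration errors are classed conditions", {
  tpl <- clade_template("Reina")
  expect_error(generate_genome(list(bg_length = 10000, insertions = list(
    insertion_spec(tpl, 2000), insertion_spec(tpl, 2050))), seed = 1),
    class = "chromoscan_config_error")
  expect_error(generate_genome(list(bg_length = 100, insertions = list(
    insertion_spec(tpl, 50))), seed = 1),
    class = "chromoscan_config_error")
  expect_error(clade_template("Reina", ppt_length = 20),
               class = "chromoscan_config_error")
  expect_error(clade_template("Reina", internal_length = 500) |>
                 insertion_spec(1000) |>
                 (\(s) generate_genome(list(bg_length = 9000,
                                            insertions = list(s)), seed = 1))(),
               class = "chromoscan_config_error")
  expect_error(generate_genome(list(bg_length = 1000)),
               class = "chromoscan_config_error")
})

test_that("clade templates enforce the layout invariants", {
  crm <- clade_template("CRM")
  expect_equal(crm$cd_relative_to_ppt, "downstream")
  expect_true(crm$orf_into_3ltr)
  expect_equal(crm$cd_group, "CR")
  for (cl in c("Tekay", "Reina", "Galadriel")) {
    tpl <- clade_template(cl)
    expect_equal(tpl$cd_relative_to_ppt, "upstream")
    expect_false(tpl$orf_into_3ltr)
    expect_equal(tpl$cd_group, "II")
  }
})

test_that("realized_divergence counts differing sites", {
  ltr <- strrep("ACGT", 158)  # 632 nt
  ltr <- substr(ltr, 1, 631)
  expect_equal(realized_divergence(ltr, ltr), 0)
  a <- strrep("A", 100)
  b <- paste0(strrep("A", 99), "T")
  expect_equal(realized_divergence(a, b), 0.01)
  expect_equal(realized_divergence(strrep("A", 50), strrep("T", 50)), 1)
  expect_error(realized_divergence("AAA", "AAAA"),
               class = "chromoscan_input_error")
})

test_that("truth writers emit readable GFF3 and TSV", {
  sim <- fixture_sim()
  tf <- withr::local_tempfile(fileext = ".gff3")
  write_truth_gff3(sim$truth, tf)
  lines <- readLines(tf)
  expect_equal(lines[1], "##gff-version 3")
  body <- read.table(tf, sep = "\t", comment.char = "#")
  expect_true(all(body$V4 <= body$V5))   # 1-based inclusive
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_truth_tsv(sim$truth, tsv)
  back <- read.table(tsv, sep = "\t", header = TRUE)
  expect_equal(nrow(back), nrow(sim$truth))
})
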