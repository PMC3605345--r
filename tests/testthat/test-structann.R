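# PBS / PPT / ORF / domain annotation and the completeness rules.

test_that("detect_pbs enforces the 3-nt offset and 8/12 match floor", {
  motif <- DEFAULT_PBS_MOTIF
  ltr <- strrep("C", 100)
  mk <- function(gap, pbs) paste0(ltr, strrep("T", gap), pbs, strrep("C", 50))
  hit <- detect_pbs(mk(1, motif), 100)
  expect_equal(hit$offset_from_5ltr, 1)
  expect_equal(hit$match_length, 12)
  expect_equal(hit$mismatches, 0)
  expect_equal(hit$start, 101)

  expect_null(detect_pbs(mk(4, motif), 100))

  # 7 of 12 matching (5 spread mismatches): below both floors
  bad <- motif
  for (i in c(2, 5, 7, 9, 12))
    substr(bad, i, i) <- chartr("ACGT", "CATG", substr(bad, i, i))
  expect_null(detect_pbs(mk(0, bad), 100))

  # one mismatch still accepted
  one <- motif; substr(one, 6, 6) <- chartr("ACGT", "CATG", substr(one, 6, 6))
  h1 <- detect_pbs(mk(0, one), 100)
  expect_equal(h1$mismatches, 1)
})

test_that("detect_ppt reports runs of 7-14 purines with roles", {
  # 13-purine run abutting the LTR
  e <- paste0(strrep("C", 200), "AGGGAGAAGGGAG", strrep("T", 100))
  calls <- detect_ppt(e, 213)
  expect_length(calls, 1)
  expect_equal(calls[[1]]$role, "functional")
  expect_equal(calls[[1]]$length, 13)
  expect_equal(calls[[1]]$end, 213)

  # 6-purine run: no call
  e6 <- paste0(strrep("C", 200), "AGGAGA", strrep("T", 100))
  expect_length(detect_ppt(e6, 206), 0)

  # overlength run trimmed to its 3'-most 14 nt
  e20 <- paste0(strrep("C", 200), strrep("AG", 10), strrep("T", 100))
  c20 <- detect_ppt(e20, 220)
  expect_length(c20, 1)
  expect_true(c20[[1]]$overlength)
  expect_equal(c20[[1]]$length, 14)
  expect_equal(c20[[1]]$end, 220)

  # additional + functional (Bongo3-like PPT_a layout)
  tpl <- clade_template("Tekay", has_ppt_a = TRUE)
  gen <- generate_genome(list(bg_length = 16000, insertions = list(
    insertion_spec(tpl, 3000))), seed = 8)
  tr <- gen$truth[1, ]
  elem <- substr(gen$genome[[1]], tr$start + 1, tr$end)
  calls <- detect_ppt(elem, tr$ltr3_start - tr$start)
  roles <- vapply(calls, `[[`, "", "role")
  expect_equal(sum(roles == "functional"), 1)
  expect_gte(sum(roles == "additional"), 1)
  # the planted PPT_a is among the additional calls
  ppt_a <- c(tr$ppt_a_start, tr$ppt_a_end) - tr$start
  expect_true(any(vapply(calls, function(p)
    p$role == "additional" && p$start <= ppt_a[1] && p$end >= ppt_a[2], TRUE)))
})

test_that("detect_ppt is invariant to content outside the search window", {
  e1 <- paste0(strrep("A", 50), strrep("C", 2000), "AGAGAGAG", strrep("T", 60))
  e2 <- paste0(strrep("G", 50), strrep("C", 2000), "AGAGAGAG", strrep("T", 60))
  l3 <- 50 + 2000 + 8
  expect_identical(detect_ppt(e1, l3), detect_ppt(e2, l3))
})

test_that("find_gag_pol_orf flags disruption and LTR read-through", {
  anns <- fixture_annotations()
  sim <- fixture_sim()
  for (i in seq_along(anns)) {
    ann <- anns[[i]]
    expect_false(ann$orf$disrupted)
    if (sim$truth$clade[i] == "CRM") expect_true(ann$orf$extends_into_3ltr)
  }
  # injected premature stop -> disrupted
  gen <- generate_genome(list(bg_length = 16000, insertions = list(
    insertion_spec(clade_template("Reina"), 3000, disrupt_orf = TRUE))),
    seed = 13)
  tr <- gen$truth[1, ]
  elem <- substr(gen$genome[[1]], tr$start + 1, tr$end)
  orf <- find_gag_pol_orf(elem, tr$ltr5_end - tr$start, tr$ltr3_start - tr$start)
  expect_true(orf$disrupted)
})

test_that("scan_domains finds the cassette in order and rejects shuffles", {
  panel <- chromo_reference_panel()
  pep <- panel$clades$Tekay
  protein <- paste0("M", pep$GAG_ZF, pep$PR, pep$RT, pep$RH, pep$INT, pep$CD)
  hits <- scan_domains(protein)
  expect_true(all(c("GAG_ZF", "PR", "RT", "RH", "INT_ZF_HHCC", "INT_DD35E",
                    "INT_GPFY", "CD") %in% hits$name))
  hhcc <- hits$aa_start[hits$name == "INT_ZF_HHCC"]
  dd <- hits$aa_start[hits$name == "INT_DD35E"]
  gp <- hits$aa_start[hits$name == "INT_GPFY"]
  expect_true(hhcc < dd && dd < gp)
  # exact exemplar scores at the exact offset
  rt_hit <- hits[hits$name == "RT", ]
  expect_equal(rt_hit$aa_start, 1 + nchar(pep$GAG_ZF) + nchar(pep$PR) + 1)

  # shuffled-sequence false-positive rate < 1% (scaled to 400 shuffles for
  # runtime; threshold untouched)
  set.seed(5)
  v <- strsplit(protein, "")[[1]]
  fp <- 0L
  for (i in 1:400) {
    shuf <- paste(sample(v, 300), collapse = "")
    s <- scan_domains(shuf)
    if (nrow(s[s$name != "NLS", ])) fp <- fp + 1L
  }
  expect_lt(fp / 400, 0.01)
  expect_error(scan_domains(protein, profiles = list()),
               class = "chromoscan_config_error")
})

test_that("classify_completeness applies the full-length rules", {
  anns <- fixture_annotations()
  expect_true(all(vapply(anns, `[[`, "", "completeness") == "full_length"))
  # remove the TSD -> incomplete
  a <- anns[[1]]
  a$tsd <- structure(list(present = FALSE, edge = FALSE), class = "tsd_call")
  expect_equal(classify_completeness(a), "incomplete")
  # no recognizable domains at all -> degenerate
  a$domains <- a$domains[0, ]
  a$rt_aux <- NULL
  a$cd_call <- list(group = "unclassified")
  expect_equal(classify_completeness(a), "degenerate")
})

test_that("element-local coordinates round-trip to genome space", {
  sim <- fixture_sim()
  anns <- fixture_annotations()
  for (i in seq_along(anns)) {
    ann <- anns[[i]]
    tr <- sim$truth[i, ]
    es <- ann$cand$ltr5_start
    expect_equal(es, tr$ltr5_start)
    # PBS local + element start == truth genome coordinates
    expect_equal(es + ann$pbs$start, tr$pbs_start)
    expect_equal(es + ann$pbs$end, tr$pbs_end)
    fppt <- Filter(function(p) p$role == "functional", ann$ppts)[[1]]
    expect_equal(es + fppt$start, tr$ppt_start)
    expect_equal(es + fppt$end, tr$ppt_end)
  }
})

test_that("locate_insertion_in_reference reports position, strand, TSD", {
  set.seed(21)
  ref <- random_dna(1800, 0.5)
  elem <- random_dna(4000, 0.4)
  implant <- function(pos, orient) {
    tsd <- substr(ref, pos + 1, pos + 5)
    body <- if (orient == "-") revcomp(elem) else elem
    paste0(substr(ref, 1, pos + 5), body, substr(ref, pos + 1, 1800))
  }
  # opposite orientation at position 736
  contig <- implant(736, "-")
  fl <- substr(contig, 741 - 39, 741)
  fr <- substr(contig, 742 + 4000, 742 + 4000 + 39)
  res <- locate_insertion_in_reference(fl, fr, ref, element_strand = "-")
  expect_true(res$located)
  expect_equal(res$position, 736)
  expect_equal(res$orientation, "opposite")
  expect_equal(res$tsd, substr(ref, 737, 741))
  # same orientation at position 100
  contig2 <- implant(100, "+")
  fl2 <- substr(contig2, 105 - 39, 105)
  fr2 <- substr(contig2, 106 + 4000, 106 + 4000 + 39)
  res2 <- locate_insertion_in_reference(fl2, fr2, ref, element_strand = "+")
  expect_true(res2$located)
  expect_equal(res2$position, 100)
  expect_equal(res2$orientation, "same")
  # unrelated flanks
  res3 <- locate_insertion_in_reference(random_dna(40), random_dna(40), ref)
  expect_false(res3$located)
  expect_error(locate_insertion_in_reference("ACGT", "ACGT", ref),
               class = "chromoscan_input_error")
})
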