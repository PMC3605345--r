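# RT mining, identity statistics, neighbor joining, bootstrap, MSA,
# family clustering, EST screening.

test_that("mine_rt_domains finds each implanted RT and nothing else", {
  sim <- fixture_sim()
  hits <- mine_rt_domains(sim$genome)
  expect_equal(nrow(hits), nrow(sim$truth))
  expect_true(all(hits$score > 50))
  expect_true(all(nchar(hits$peptide) > 200))
  # each hit falls inside a truth ORF span
  for (i in seq_len(nrow(hits)))
    expect_true(any(hits$nt_start[i] >= sim$truth$start &
                    hits$nt_end[i] <= sim$truth$end))
  # random sequence: no hits
  set.seed(19)
  expect_equal(nrow(mine_rt_domains(c(r = random_dna(30000)))), 0)
  # a 150-aa RT fragment is rejected by the length rule
  panel <- chromo_reference_panel()
  frag <- substr(panel$clades$Reina$RT, 1, 150)
  set.seed(8)
  frag_nt <- paste0("TTTAA", chromoscan:::reverse_translate(frag), "TAATT")
  expect_equal(nrow(mine_rt_domains(c(f = frag_nt))), 0)
})

test_that("pairwise_identity matches counting oracles", {
  expect_equal(pairwise_identity("ACDEFG", "ACDEFG"), 1.0)
  expect_equal(pairwise_identity("ACDEFG", "ACDEYG"), 5 / 6)
  # construction at known identity 0.8, no indels
  set.seed(4)
  a <- paste(sample(c("A","C","D","E","F","G","H","I","K","L"), 400,
                    replace = TRUE), collapse = "")
  b <- mutate_every_kth_aa(a, 5)     # exactly 80 of 400 changed
  expect_equal(pairwise_identity(a, b), 0.8, tolerance = 0.02)
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  expect_error(pairwise_identity("", "ACD"), class = "chromoscan_input_error")
})

test_that("identity_stats reproduces closed-form cases", {
  m <- matrix(c(1, .7, .7, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  st <- identity_stats(m, c(a = "X", b = "X"))
  expect_equal(st$median, 0.7)
  expect_equal(st$mean, 0.7)
  expect_equal(st$n_pairs, 1)

  m3 <- diag(1, 3); dimnames(m3) <- list(letters[1:3], letters[1:3])
  m3[1, 2] <- m3[2, 1] <- 0.6
  m3[1, 3] <- m3[3, 1] <- 0.7
  m3[2, 3] <- m3[3, 2] <- 0.8
  st3 <- identity_stats(m3, setNames(rep("X", 3), letters[1:3]))
  expect_equal(st3$median, 0.7)
  expect_equal(st3$mean, 0.7)
  # singleton clade: n reported, dispersion absent
  st1 <- identity_stats(m3, setNames(c("X", "X", "Y"), letters[1:3]))
  expect_equal(st1$n[st1$clade == "Y"], 1)
  expect_true(is.na(st1$median[st1$clade == "Y"]))
})

test_that("neighbor joining matches the 3-taxon closed form and additivity", {
  D <- matrix(c(0, .2, .4, .2, 0, .4, .4, .4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- build_nj_tree(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 0.1)
  expect_equal(bl[["B"]], 0.1)
  expect_equal(bl[["C"]], 0.3)

  # additive 5-taxon matrix: exact topology and branch lengths
  set.seed(12)
  gen <- ape::rtree(5, rooted = FALSE)
  gen$edge.length <- runif(nrow(gen$edge), 0.05, 1)
  D5 <- stats::cophenetic(gen)
  mine <- build_nj_tree(D5)
  expect_equal(ape::dist.topo(ape::unroot(gen), mine), 0, ignore_attr = TRUE)
  expect_equal(max(abs(stats::cophenetic(mine)[rownames(D5), colnames(D5)] - D5)),
               0, tolerance = 1e-9)
  # agreement with the reference implementation on a noisy matrix
  N <- as.matrix(D5) + 0.01 * (1 - diag(5))
  expect_equal(ape::dist.topo(build_nj_tree(N), ape::nj(N)), 0,
               ignore_attr = TRUE)

  # degenerate all-zero matrix: all branch lengths zero
  Z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  tz <- build_nj_tree(Z)
  expect_true(all(tz$edge.length == 0))
  # non-symmetric input rejected
  B <- D; B[1, 2] <- 0.9
  expect_error(build_nj_tree(B), class = "chromoscan_input_error")
})

test_that("bootstrap supports are seeded, convergent, and separate clades", {
  # two clearly separated clades
  set.seed(6)
  base <- paste(sample(c("A","C","D","E","F","G","H","I","K","L"), 120,
                       replace = TRUE), collapse = "")
  cladeA <- vapply(1:3, function(i) mutate_every_kth_aa(base, 10 + i), "")
  far <- mutate_every_kth_aa(base, 2)
  cladeB <- vapply(1:3, function(i) mutate_every_kth_aa(far, 10 + i), "")
  msa <- setNames(c(cladeA, cladeB), c(paste0("A", 1:3), paste0("B", 1:3)))
  t1 <- bootstrap_supports(msa, n_replicates = 100, seed = 2)
  t2 <- bootstrap_supports(msa, n_replicates = 100, seed = 2)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  # the A|B separating edge has support >= 95
  key_support <- max(as.numeric(t1$node.label[t1$node.label != ""]))
  expect_gte(key_support, 95)
  # no supports when n_replicates = 0
  t0 <- bootstrap_supports(msa, n_replicates = 0)
  expect_null(t0$node.label)
})

test_that("center-star MSA projects gaps consistently", {
  peps <- c(a = "MKVLITAGDE", b = "MKVLITAGDE", c = "MKVLITAGDE")
  msa <- center_star_msa(peps)
  expect_identical(unname(msa), unname(peps))   # gap-free
  # a 3-aa insertion in one row opens one 3-column block in all others
  peps2 <- c(a = "MKVLITAGDEWWR", b = "MKVLWWWITAGDEWWR", c = "MKVLITAGDEWWR")
  msa2 <- center_star_msa(peps2, center = "a")
  expect_equal(unique(nchar(msa2)), 16)
  expect_equal(msa2[["a"]], "MKVL---ITAGDEWWR")
  expect_equal(msa2[["b"]], "MKVLWWWITAGDEWWR")
  expect_error(center_star_msa(character(0)), class = "chromoscan_input_error")
})

test_that("family clustering is single-linkage with inclusive threshold", {
  set.seed(44)
  base <- random_dna(500, 0.4)
  # identity 0.85: same family; 0.70: different; exactly 0.80: same
  pair <- function(k) c(x = base, y = mutate_every_kth(base, k))
  f85 <- cluster_families(pair(7))          # ~0.857 identity
  expect_equal(f85[["x"]], f85[["y"]])
  f70 <- cluster_families(pair(3))          # ~0.666
  expect_false(f70[["x"]] == f70[["y"]])
  f80 <- cluster_families(pair(5))          # exactly 0.80
  expect_equal(ltr_identity(base, mutate_every_kth(base, 5)), 0.8)
  expect_equal(f80[["x"]], f80[["y"]])
  # single linkage chains through an intermediate
  chain <- c(a = base, b = mutate_every_kth(base, 6), # 0.833 to a
             c = mutate_every_kth(mutate_every_kth(base, 6), 7))
  fc <- cluster_families(chain)
  expect_equal(length(unique(fc)), 1)
})

test_that("est_screen applies the 80% / 600 nt retention rule", {
  sim <- fixture_sim()
  tr <- sim$truth[1, ]
  elem <- substr(sim$genome[[1]], tr$start + 1, tr$end)
  lib <- c(elem1 = elem)
  mk_transcript <- function(len, k) {
    t <- substr(elem, 1001, 1000 + len)
    mutate_every_kth(t, k)
  }
  tx <- c(good = mk_transcript(700, 10),     # ~90% identity, 700 nt
          short = mk_transcript(500, 20),    # 95% identity but 500 nt
          junk = local({ set.seed(2); random_dna(700) }))
  res <- est_screen(tx, lib)
  expect_true(res$retained[res$transcript_id == "good"])
  expect_false(res$retained[res$transcript_id == "short"])
  expect_false(res$retained[res$transcript_id == "junk"])
  expect_error(est_screen(tx, character(0)),
               class = "chromoscan_config_error")
})
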