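# Session-cached fixtures: one moderate synthetic genome with its detection
# and annotation results, shared across test files to keep the suite fast.

.fixtures <- new.env(parent = emptyenv())

fixture_sim <- function() {
  if (is.null(.fixtures$sim))
    .fixtures$sim <- simulate_chromovirus_genome(n_elements = 8, seed = 101,
                                                 divergence_range = c(0, 0.04))
  .fixtures$sim
}

fixture_annotations <- function() {
  if (is.null(.fixtures$anns)) {
    sim <- fixture_sim()
    g <- sim$genome[[1]]
    cands <- find_ltr_pairs(sim$genome)
    .fixtures$cands <- cands
    .fixtures$anns <- lapply(seq_len(nrow(cands)), function(i) {
      cand <- refine_boundaries(g, as.list(cands[i, ]))
      annotate_element(g, cand)
    })
  }
  .fixtures$anns
}

fixture_candidates <- function() {
  fixture_annotations()
  .fixtures$cands
}

# deterministic mutated copy: substitute every k-th position cyclically
mutate_every_kth <- function(seq, k) {
  v <- strsplit(seq, "")[[1]]
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  idx <- seq(1L, length(v), by = k)
  v[idx] <- rot[v[idx]]
  paste(v, collapse = "")
}

# peptide analogue: rotate every k-th residue within the 20-letter alphabet
mutate_every_kth_aa <- function(pep, k) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  rot <- setNames(aa[c(2:20, 1)], aa)
  v <- strsplit(pep, "")[[1]]
  idx <- seq(1L, length(v), by = k)
  v[idx] <- rot[v[idx]]
  paste(v, collapse = "")
}
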