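# Ungapped position-specific scoring matrices (log2 odds vs a uniform
# amino-acid background) built from the bundled reference panel.  Fixed-length
# PSSMs scanned at every offset stand in for full profile HMMs; thresholds are
# set at half the weakest training-sequence self-score, which keeps the
# shuffled-sequence false-positive rate well below 1%.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Build a PSSM from equal-length ungapped peptides
#'
#' @param peptides character vector of equal-length training peptides.
#' @param pseudocount total pseudocount mass spread over the background.
#' @return object of class `chromo_pssm` with the score matrix (bits), the
#'   profile width, and a detection threshold (half the minimum training
#'   self-score).
#' @export
build_pssm <- function(peptides, pseudocount = 1) {
  w <- unique(nchar(peptides))
  if (length(w) != 1L) stop_config("PSSM training peptides must be equal length")
  n <- length(peptides)
  q <- 1 / length(AA20)
  mat <- matrix(0, nrow = length(AA20) + 1L, ncol = w,
                dimnames = list(c(AA20, "other"), NULL))
  chars <- lapply(peptides, seq_chars)
  for (j in seq_len(w)) {
    col <- vapply(chars, `[[`, "", j)
    cnt <- table(factor(col, levels = AA20))
    p <- (as.numeric(cnt) + pseudocount * q) / (n + pseudocount)
    mat[seq_along(AA20), j] <- log2(p / q)
  }
  obj <- structure(list(mat = mat, width = w, n_train = n), class = "chromo_pssm")
  self <- vapply(peptides, function(p) max(scan_pssm_scores(obj, p)), 0)
  obj$threshold <- 0.5 * min(self)
  obj
}

pep_to_idx <- function(pep) {
  i <- match(seq_chars(pep), AA20)
  i[is.na(i)] <- length(AA20) + 1L
  i
}

# Score every offset of `pep` against the PSSM; returns a numeric vector of
# length (len - width + 1), or numeric(0) when the peptide is shorter.
scan_pssm_scores <- function(pssm, pep) {
  idx <- pep_to_idx(pep)
  w <- pssm$width
  n_off <- length(idx) - w + 1L
  if (n_off < 1L) return(numeric(0))
  sc <- numeric(n_off)
  m <- pssm$mat
  for (j in seq_len(w)) sc <- sc + m[cbind(idx[j:(j + n_off - 1L)], j)]
  sc
}

# Best hit of one profile in a peptide (or NULL below threshold).
pssm_best_hit <- function(pssm, pep, threshold = pssm$threshold) {
  sc <- scan_pssm_scores(pssm, pep)
  if (!length(sc)) return(NULL)
  o <- which.max(sc)
  if (sc[o] < threshold) return(NULL)
  list(aa_start = o, aa_end = o + pssm$width - 1L, score = sc[o])
}

# ---- bundled panel ----------------------------------------------------------

.panel_env <- new.env(parent = emptyenv())

#' Bundled synthetic reference panel
#'
#' Clade exemplar peptides (GAG zinc finger, protease, RT, RNaseH, integrase,
#' chromodomain) for the four plant chromoviral clades, an HP1-like reference
#' chromodomain with annotated aromatic-cage columns, and PSSM profiles built
#' from the exemplars.  All peptides are synthetic stand-ins generated once
#' from a shared scaffold (see `inst/extdata/synthetic_domain_panel.faa`);
#' they carry the canonical catalytic motifs (CCHC, DTG, LPQG/YIDD, DEDD,
#' HHCC + DD35E + GPF/GPY) at fixed positions.
#'
#' @return list with elements `clades` (per-clade peptide lists), `hp1`
#'   (reference chromodomain), `cage_columns`, and `profiles` (named list of
#'   `chromo_pssm`).
#' @export
chromo_reference_panel <- function() {
  if (!is.null(.panel_env$panel)) return(.panel_env$panel)
  clades <- .panel_peptides
  slice <- function(dom, cols)
    vapply(clades, function(p) paste(seq_chars(p[[dom]])[cols], collapse = ""), "")
  profiles <- list(
    GAG_ZF = build_pssm(vapply(clades, `[[`, "", "GAG_ZF")),
    PR     = build_pssm(vapply(clades, `[[`, "", "PR")),
    RT     = build_pssm(vapply(clades, `[[`, "", "RT")),
    RH     = build_pssm(vapply(clades, `[[`, "", "RH")),
    INT_ZF_HHCC = build_pssm(slice("INT", .int_zf_cols)),
    INT_DD35E   = build_pssm(slice("INT", .int_dd35e_cols)),
    INT_GPFY    = build_pssm(slice("INT", .int_gpfy_cols)),
    CD     = build_pssm(vapply(clades, `[[`, "", "CD")))
  .panel_env$panel <- list(clades = clades, hp1 = .hp1_chromodomain,
                           cage_columns = .hp1_cage_columns,
                           profiles = profiles)
  .panel_env$panel
}
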