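# Alignment wrappers.  One nucleotide scoring scheme (match +1, mismatch -1,
# gap open -4, gap extend -1) is shared by LTR-pair validation, family
# clustering and LTR-divergence dating so that "identity" means the same
# quantity everywhere.  Protein alignments use BLOSUM62 with affine gaps
# (open 11, extend 1).

.blosum_env <- new.env(parent = emptyenv())
blosum62 <- function() {
  if (is.null(.blosum_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_env$m <- e$BLOSUM62
  }
  .blosum_env$m
}

# Global alignment of two nucleotide strings under the package scheme.
align_ltr <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  Biostrings::pairwiseAlignment(a, b, substitutionMatrix = mat,
                                gapOpening = 4, gapExtension = 1,
                                type = "global")
}

align_protein <- function(a, b, type = "global") {
  Biostrings::pairwiseAlignment(a, b, substitutionMatrix = blosum62(),
                                gapOpening = 11, gapExtension = 1, type = type)
}

aligned_chars <- function(al) {
  list(p = seq_chars(as.character(Biostrings::alignedPattern(al))),
       s = seq_chars(as.character(Biostrings::alignedSubject(al))))
}

# Identity = identical columns / all aligned columns (gap columns count in
# the denominator).  Strict but stable under indels.
alignment_identity <- function(al) {
  ac <- aligned_chars(al)
  sum(ac$p == ac$s & ac$p != "-") / length(ac$p)
}

# Identity over non-gap columns only (both residues present).
alignment_identity_ungapped <- function(al) {
  ac <- aligned_chars(al)
  keep <- ac$p != "-" & ac$s != "-"
  if (!any(keep)) return(NA_real_)
  sum(ac$p[keep] == ac$s[keep]) / sum(keep)
}

# p-distance over non-gap aligned columns, plus the span used.
alignment_p_distance <- function(al) {
  ac <- aligned_chars(al)
  keep <- ac$p != "-" & ac$s != "-"
  n <- sum(keep)
  list(p = if (n) sum(ac$p[keep] != ac$s[keep]) / n else NA_real_,
       aligned_span = n,
       gap_columns = length(ac$p) - n)
}

#' Nucleotide identity between two LTR (or any DNA) sequences
#'
#' Global alignment under the package-wide scoring scheme (match +1,
#' mismatch -1, gap open -4, gap extend -1); identity is the fraction of
#' identical columns over all aligned columns, gap columns included.
#'
#' @param a,b nucleotide strings.
#' @return fraction in \[0, 1\].
#' @export
ltr_identity <- function(a, b) alignment_identity(align_ltr(a, b))
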