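# Insertion-age estimation from LTR-pair divergence via the molecular clock
# t = K / (2 r): the two LTRs are identical at integration and accumulate
# substitutions independently, so their divergence K divided by twice the
# per-year substitution rate r dates the insertion.

#' Default substitution rate (substitutions/site/year)
#'
#' Average synonymous substitution rate for dicot nuclear loci, the
#' conventional clock for dating plant LTR retrotransposon insertions.
#' @export
DEFAULT_SUBSTITUTION_RATE <- 1.5e-8

#' LTR-pair divergence
#'
#' Global alignment under the package nucleotide scheme; the p-distance is
#' computed over non-gap aligned columns only (gap columns excluded from
#' numerator and denominator).  Optionally Jukes-Cantor corrected.
#'
#' @param ltr5,ltr3 LTR sequences (each >= 50 nt).
#' @param metric "p_distance" (default) or "jc" (Jukes-Cantor corrected).
#' @return list: `K`, `p`, `aligned_span` (non-gap columns), `partial_ltr`
#'   (LTR lengths differ by more than 10%), `metric`.
#' @export
ltr_divergence <- function(ltr5, ltr3, metric = c("p_distance", "jc")) {
  metric <- match.arg(metric)
  if (nchar(ltr5) < 50L || nchar(ltr3) < 50L)
    stop_input("LTR sequences must each be at least 50 nt")
  al <- align_ltr(ltr5, ltr3)
  pd <- alignment_p_distance(al)
  if (pd$aligned_span < 50L)
    stop_input("aligned LTR overlap below 50 columns: insufficient signal")
  K <- if (metric == "jc") {
    if (pd$p >= 0.75) stop_input("p-distance %.3f too large for JC correction", pd$p)
    -0.75 * log(1 - 4 * pd$p / 3)
  } else pd$p
  lens <- c(nchar(ltr5), nchar(ltr3))
  list(K = K, p = pd$p, aligned_span = pd$aligned_span,
       partial_ltr = (min(lens) / max(lens)) < 0.9, metric = metric)
}

#' Insertion age from LTR divergence
#'
#' t = K / (2 r), exactly.
#'
#' @param K substitutions per site between the LTR pair (fraction; 0.0288
#'   for a printed divergence of 2.88%).
#' @param r substitution rate per site per year (default
#'   [DEFAULT_SUBSTITUTION_RATE]).
#' @param aligned_span,partial_ltr carried through from [ltr_divergence()].
#' @return list of class `age_estimate`: `K`, `r`, `t_years`, `t_mya`,
#'   `aligned_span`, `partial_ltr`.
#' @export
estimate_age <- function(K, r = DEFAULT_SUBSTITUTION_RATE,
                         aligned_span = NA_integer_, partial_ltr = FALSE) {
  if (r <= 0) stop_config("substitution rate r must be positive")
  if (K < 0) stop_input("K must be non-negative")
  t_years <- K / (2 * r)
  structure(list(K = K, r = r, t_years = t_years, t_mya = t_years / 1e6,
                 aligned_span = aligned_span, partial_ltr = partial_ltr),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf("K = %.4f, r = %g /site/year -> t = %s Mya%s\n", x$K, x$r,
              signif(x$t_mya, 3), if (x$partial_ltr) " (partial LTR)" else ""))
  invisible(x)
}

#' Reference table of Beta vulgaris chromoviruses
#'
#' The printed per-element statistics for the 21 full-length sugar-beet
#' chromoviruses (name, clade, total length, LTR lengths, TSD, LTR
#' divergence in percent and printed age in Mya).  Parenthesized
#' divergence/age entries in the source (partial-LTR estimates) are marked
#' `partial`; two printed ages are inconsistent with t = K/(2r) at
#' r = 1.5e-8 (apparent typos) and carry `age_consistent = FALSE`.
#'
#' @return data.frame.
#' @export
beta_chromovirus_table <- function() {
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = '
name      clade     total ltr5 ltr3 tsd    divergence_pct age_mya partial
Beetle3   CRM       5917  744  742  GTAWA  2.47  0.82   FALSE
Beetle3-1 CRM       5908  753  753  AGGAG  3.68  1.225  FALSE
Beetle4   CRM       6175  886  889  TAATA  4.07  1.35   FALSE
Beetle4-1 CRM       6182  886  890  TAATA  4.06  1.35   FALSE
Beetle4-2 CRM       6169  885  885  CAACA  1.25  0.42   FALSE
Beetle5   CRM       6654  1339 679  AACKA  1.79  0.6    FALSE
Beetle5-1 CRM       5941  659  637  TATCA  2.88  0.96   FALSE
Beetle5-2 CRM       5961  679  675  CAATA  3.96  1.32   FALSE
Beetle6   CRM       5315  624  422  TCAGG  2.91  0.9    TRUE
Beetle7   CRM       6695  1086 1086 ACAAM  2.62  0.87   FALSE
Bongo1    Tekay     10329 2669 3000 AAAAT  5.23  1.75   FALSE
Bongo2    Tekay     8417  1049 2743 TAGTA  3.84  1.29   TRUE
Bongo3    Tekay     11565 2561 2561 GAGCG  0.08  0.026  FALSE
Bingo1    Reina     5811  431  430  TAAAT  0.23  0.08   FALSE
Bingo1-1  Reina     5810  425  423  GATTG  1.68  0.6    FALSE
Bingo2    Reina     5563  503  500  CTAAC  1.01  0.34   FALSE
Bingo3    Reina     5807  453  453  GTAAG  0.67  0.22   FALSE
Bingo4    Reina     5452  392  392  TGATG  0.77  0.026  FALSE
Bingo5    Reina     5320  343  337  ACCAC  1.80  0.6    FALSE
Bingo6    Reina     5261  293  293  CGCAA  1.03  0.345  FALSE
Bingo7    Reina     5476  494  494  GGGTT  1.64  0.546  FALSE
Beon1     Galadriel 6038  631  631  GTAGG  0.00  0      FALSE
')
  tab$age_consistent <- !(tab$name %in% c("Bingo4", "Bingo1-1"))
  tab
}
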