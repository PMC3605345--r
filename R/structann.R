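# Internal structure annotation: primer binding site (PBS), polypurine
# tract(s) (PPT), the gag-pol ORF, protein domain cassette, and the
# full-length / incomplete / degenerate classification.  Element-local
# coordinates are 0-based half-open and convert to genome coordinates by
# adding the element start.

#' Detect the primer binding site next to the 5' LTR
#'
#' Best ungapped placement of a motif prefix beginning within `max_offset`
#' nt of the 5' LTR end; a call requires at least `min_match` matching
#' nucleotides and at most `max_mismatch` mismatches.
#'
#' @param element_seq element sequence (character scalar).
#' @param ltr5_end element-local end of the 5' LTR (0-based half-open).
#' @param pbs_motif motif to match (default [DEFAULT_PBS_MOTIF]).
#' @param max_offset maximum distance from the 5' LTR (default 3 nt).
#' @param min_match minimum matching nucleotides (default 8 of 12).
#' @param max_mismatch mismatch budget within the placed prefix (default 1).
#' @return list of class `pbs_call` (`start`, `end`, `offset_from_5ltr`,
#'   `match_length`, `mismatches`) or NULL when absent.
#' @export
detect_pbs <- function(element_seq, ltr5_end, pbs_motif = DEFAULT_PBS_MOTIF,
                       max_offset = 3L, min_match = 8L, max_mismatch = 1L) {
  n <- nchar(element_seq)
  best <- NULL
  for (off in 0:max_offset) {
    for (L in nchar(pbs_motif):min_match) {
      s <- ltr5_end + off
      if (s + L > n) next
      mm <- hamming(substr(pbs_motif, 1L, L), subseq_chr(element_seq, s, s + L))
      matches <- L - mm
      if (matches < min_match || mm > max_mismatch) next
      if (is.null(best) || matches > best$matches) {
        best <- list(start = s, end = s + L, offset_from_5ltr = off,
                     match_length = L, mismatches = mm, matches = matches)
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$matches <- NULL
  structure(best, class = "pbs_call")
}

#' Detect polypurine tracts upstream of the 3' LTR
#'
#' Reports every maximal purine (A/G) run of length 7-14 within the search
#' window; a longer run is reported as its 3'-most 14 nt with an overlength
#' flag.  The run ending exactly at the 3' LTR is the functional PPT, any
#' other is "additional" (PPT_a-like).
#'
#' @param element_seq element sequence.
#' @param ltr3_start element-local start of the 3' LTR.
#' @param search_window nt scanned upstream of the 3' LTR (default 2000).
#' @return list of `ppt_call` lists (`start`, `end`, `length`,
#'   `adjacent_to_3ltr`, `role`, `overlength`), 5' to 3'.
#' @export
detect_ppt <- function(element_seq, ltr3_start, search_window = 2000L) {
  w0 <- max(0L, ltr3_start - search_window)
  region <- subseq_chr(element_seq, w0, ltr3_start)
  v <- seq_chars(region) %in% c("A", "G")
  if (!any(v)) return(list())
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in which(r$values & r$lengths >= 7L)) {
    s <- w0 + starts[i] - 1L; e <- w0 + ends[i]
    overlength <- (e - s) > 14L
    if (overlength) s <- e - 14L
    role <- if (e == ltr3_start) "functional" else "additional"
    out[[length(out) + 1L]] <- structure(
      list(start = s, end = e, length = e - s,
           adjacent_to_3ltr = e == ltr3_start, role = role,
           overlength = overlength), class = "ppt_call")
  }
  out
}

#' Locate the gag-pol open reading frame
#'
#' Longest stop-free stretch across the three sense-strand frames of the
#' element (stop-to-stop convention; the terminal stop codon is included in
#' the span).  `disrupted` is set when the ORF covers less than
#' `coverage_min` of the internal region.
#'
#' @param element_seq element sequence, already oriented to its sense strand.
#' @param ltr5_end,ltr3_start element-local internal-region boundaries.
#' @param coverage_min minimum ORF coverage of the internal region (default
#'   0.8) below which the element counts as disrupted.
#' @param strand reported strand tag ("+" or "-").
#' @return list of class `orf_call`: `start`, `end` (0-based half-open, stop
#'   codon included), `frame`, `strand`, `extends_into_3ltr`, `disrupted`,
#'   `protein` (translated ORF, no stop).
#' @export
find_gag_pol_orf <- function(element_seq, ltr5_end, ltr3_start,
                             coverage_min = 0.8, strand = "+") {
  n <- nchar(element_seq)
  best <- NULL
  for (frame in 0:2) {
    aa <- translate_nt(substr(element_seq, frame + 1L, n))
    if (!nchar(aa)) next
    va <- seq_chars(aa)
    stops <- which(va == "*")
    seg_starts <- c(1L, stops + 1L)
    seg_ends <- c(stops - 1L, length(va))      # aa coordinates, stop excluded
    for (i in seq_along(seg_starts)) {
      len <- seg_ends[i] - seg_starts[i] + 1L
      if (len <= 0L) next
      if (is.null(best) || len > best$len) {
        has_stop <- i <= length(stops)
        best <- list(len = len, frame = frame,
                     aa_start = seg_starts[i], aa_end = seg_ends[i],
                     has_stop = has_stop,
                     protein = paste(va[seg_starts[i]:seg_ends[i]], collapse = ""))
      }
    }
  }
  if (is.null(best)) return(NULL)
  nt_start <- best$frame + 3L * (best$aa_start - 1L)
  nt_end <- best$frame + 3L * best$aa_end + (if (best$has_stop) 3L else 0L)
  internal <- ltr3_start - ltr5_end
  ov <- max(0L, min(nt_end, ltr3_start) - max(nt_start, ltr5_end))
  stop_start <- if (best$has_stop) nt_end - 3L else NA_integer_
  structure(list(
    start = nt_start, end = nt_end, frame = best$frame, strand = strand,
    extends_into_3ltr = best$has_stop && stop_start >= ltr3_start,
    disrupted = ov < coverage_min * internal,
    protein = best$protein), class = "orf_call")
}

#' Scan a protein for the chromoviral domain cassette
#'
#' Scores every offset of each bundled PSSM profile and reports the best
#' placement per profile above its threshold, plus nuclear-localization
#' signals matched by the motif P-x-\[RK\]-K-x-K.
#'
#' @param protein_seq amino-acid string.
#' @param profiles named list of `chromo_pssm` (default: bundled panel).
#' @return data.frame of hits: `name`, `aa_start`, `aa_end` (1-based
#'   inclusive protein coordinates), `score` (bits; NA for NLS),
#'   `profile_id`; sorted by `aa_start`.
#' @export
scan_domains <- function(protein_seq, profiles = chromo_reference_panel()$profiles) {
  if (!length(profiles)) stop_config("empty profile set")
  hits <- list()
  for (nm in names(profiles)) {
    h <- pssm_best_hit(profiles[[nm]], protein_seq)
    if (!is.null(h))
      hits[[length(hits) + 1L]] <- data.frame(
        name = nm, aa_start = h$aa_start, aa_end = h$aa_end,
        score = h$score, profile_id = nm)
  }
  for (m in detect_nls(protein_seq))
    hits[[length(hits) + 1L]] <- data.frame(
      name = "NLS", aa_start = m$aa_start, aa_end = m$aa_end,
      score = NA_real_, profile_id = "NLS_regex")
  if (!length(hits))
    return(data.frame(name = character(0), aa_start = integer(0),
                      aa_end = integer(0), score = numeric(0),
                      profile_id = character(0)))
  out <- do.call(rbind, hits)
  out[order(out$aa_start), , drop = FALSE]
}

#' Classify element completeness
#'
#' `full_length` requires all of: TSD present, undisrupted ORF, every
#' cassette domain detected (the chromodomain counts when either the CD
#' profile hits or the chromodomain call is classified), a functional PPT and
#' a PBS.  An element failing any criterion but retaining an RT hit is
#' `incomplete`; anything else is `degenerate`.
#'
#' @param ann annotation bundle (see [annotate_element()]).
#' @return one of "full_length", "incomplete", "degenerate".
#' @export
classify_completeness <- function(ann) {
  dom <- ann$domains
  has <- function(nm) !is.null(dom) && nrow(dom) && nm %in% dom$name
  cd_ok <- has("CD") ||
    (!is.null(ann$cd_call) && !identical(ann$cd_call$group, "unclassified"))
  cassette <- c("GAG_ZF", "PR", "RT", "RH",
                "INT_ZF_HHCC", "INT_DD35E", "INT_GPFY")
  ok <- isTRUE(ann$tsd$present) &&
    !is.null(ann$orf) && !isTRUE(ann$orf$disrupted) &&
    all(vapply(cassette, has, TRUE)) && cd_ok &&
    any(vapply(ann$ppts, function(p) p$role == "functional", TRUE)) &&
    !is.null(ann$pbs)
  if (ok) return("full_length")
  if (has("RT") || !is.null(ann$rt_aux)) "incomplete" else "degenerate"
}

# ---- full element annotation -------------------------------------------------

annotate_oriented <- function(elem, l5e, l3s, pbs_motif, panel, coverage_min = 0.8,
                              strand = "+") {
  pbs <- detect_pbs(elem, l5e, pbs_motif)
  ppts <- detect_ppt(elem, l3s)
  orf <- find_gag_pol_orf(elem, l5e, l3s, coverage_min, strand = strand)
  domains <- if (!is.null(orf) && nchar(orf$protein) >= 30L)
    scan_domains(orf$protein, panel$profiles) else NULL
  score <- (!is.null(pbs)) +
    any(vapply(ppts, function(p) p$role == "functional", TRUE)) +
    (!is.null(orf) && !orf$disrupted) +
    (!is.null(domains) && nrow(domains) && "RT" %in% domains$name)
  list(pbs = pbs, ppts = ppts, orf = orf, domains = domains,
       score = score, strand = strand)
}

#' Annotate one LTR-pair candidate
#'
#' Extracts the element, determines its sense strand (the orientation in
#' which PBS, functional PPT, intact ORF and RT evidence accumulate), and
#' assembles the full annotation bundle including the chromodomain call and
#' clade assignment.
#'
#' @param seq contig sequence (character scalar or single-element set).
#' @param cand candidate row from [find_ltr_pairs()] / [refine_boundaries()].
#' @param pbs_motif PBS motif searched next to the 5' LTR.
#' @param tsd_length,max_tsd_mismatch TSD validation settings.
#' @param panel reference panel (default bundled).
#' @param coverage_min ORF coverage defining "undisrupted" (default 0.8).
#' @return annotation bundle (list): candidate coordinates, `strand`, `tsd`,
#'   `pbs`, `ppts`, `orf`, `domains`, `cd_call`, `clade_call`,
#'   `completeness`, `ltr5_seq`, `ltr3_seq`, `element_seq` (sense strand).
#' @export
annotate_element <- function(seq, cand, pbs_motif = DEFAULT_PBS_MOTIF,
                             tsd_length = 5L, max_tsd_mismatch = 0L,
                             panel = chromo_reference_panel(),
                             coverage_min = 0.8) {
  seq <- as_seq_set(seq)[[1]]
  elem <- subseq_chr(seq, cand$ltr5_start, cand$ltr3_end)
  n <- nchar(elem)
  l5e <- cand$ltr5_end - cand$ltr5_start
  l3s <- cand$ltr3_start - cand$ltr5_start
  fwd <- annotate_oriented(elem, l5e, l3s, pbs_motif, panel, coverage_min, "+")
  rc <- revcomp(elem)
  rev <- annotate_oriented(rc, n - l3s, n - l5e, pbs_motif, panel,
                           coverage_min, "-")
  ann <- if (rev$score > fwd$score) rev else fwd
  sense <- if (ann$strand == "-") rc else elem
  sl5e <- if (ann$strand == "-") n - l3s else l5e
  sl3s <- if (ann$strand == "-") n - l5e else l3s
  ann$element_seq <- sense
  ann$ltr5_end_local <- sl5e
  ann$ltr3_start_local <- sl3s
  ann$ltr5_seq <- subseq_chr(sense, 0L, sl5e)
  ann$ltr3_seq <- subseq_chr(sense, sl3s, n)
  ann$cand <- cand
  ann$seq_id <- cand$seq_id %||% "seq"
  ann$tsd <- detect_tsd(seq, cand, tsd_length, max_tsd_mismatch)
  ann$cd_call <- extract_chromodomain(ann, panel)
  rt_pep <- NULL
  if (!is.null(ann$domains) && "RT" %in% ann$domains$name) {
    r <- ann$domains[ann$domains$name == "RT", ][1L, ]
    rt_pep <- substr(ann$orf$protein, r$aa_start, r$aa_end)
  } else {
    # a premature stop can push the RT out of the longest ORF; rescue it by
    # a six-frame scan of the element so disrupted copies still classify
    aux <- mine_rt_domains(setNames(sense, "element"), panel)
    if (nrow(aux)) {
      ann$rt_aux <- aux[which.max(aux$score), , drop = FALSE]
      rt_pep <- ann$rt_aux$peptide
    }
  }
  ann$clade_call <- assign_clade(ann$cd_call, rt_pep, panel)
  ann$completeness <- classify_completeness(ann)
  ann
}

#' Locate an insertion site in a reference gene
#'
#' Places the element's two flanking sequences (the left flank ending with
#' the TSD, the right flank starting with it) in a reference sequence on
#' either strand, and reports the 1-based reference coordinate immediately 5'
#' of the TSD on the reference sense strand.
#'
#' @param flank_left,flank_right flanking sequences, each at least 20 nt.
#' @param reference reference gene sequence.
#' @param tsd_length TSD length (default 5).
#' @param element_strand strand of the element relative to the flanks.
#' @param max_mismatch per-flank mismatch tolerance (default 2).
#' @return list: `located`, and when located `position` (1-based),
#'   `orientation` ("same"/"opposite" relative to reference transcription),
#'   `tsd`.
#' @export
locate_insertion_in_reference <- function(flank_left, flank_right, reference,
                                          tsd_length = 5L,
                                          element_strand = "+",
                                          max_mismatch = 2L) {
  if (nchar(flank_left) < 20L || nchar(flank_right) < 20L)
    stop_input("flanks must each be at least 20 nt")
  reference <- as_seq_set(reference)[[1]]
  Lr <- nchar(reference)
  find_one <- function(pat, ref) {
    m <- Biostrings::matchPattern(pat, Biostrings::DNAString(ref),
                                  max.mismatch = max_mismatch)
    if (!length(m)) return(NULL)
    c(start = BiocGenerics::start(m)[1L], end = BiocGenerics::end(m)[1L])
  }
  for (ref_strand in c("+", "-")) {
    ref <- if (ref_strand == "+") reference else revcomp(reference)
    l <- find_one(flank_left, ref)
    r <- find_one(flank_right, ref)
    if (is.null(l) || is.null(r)) next
    # at the pre-insertion locus the two flanks overlap by exactly the TSD
    if (l[["end"]] - r[["start"]] + 1L != tsd_length) next
    tsd <- substr(ref, r[["start"]], l[["end"]])
    pos <- if (ref_strand == "+") r[["start"]] - 1L
           else (Lr - l[["end"]] + 1L) - 1L
    orientation <- if ((ref_strand == "+") == (element_strand == "+"))
      "same" else "opposite"
    return(list(located = TRUE, position = pos, orientation = orientation,
                tsd = tsd))
  }
  list(located = FALSE)
}
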