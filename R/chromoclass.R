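# Chromodomain extraction and clade assignment.  The chromodomain window is
# taken downstream of the integrase GPF/GPY motif (Tekay/Reina/Galadriel
# layout) or, for the CRM layout, from the functional PPT to the ORF stop
# inside the 3' LTR.  Group I/II calls read the three aromatic-cage columns
# off a free-end-gap alignment to the bundled HP1-like reference
# chromodomain; the CR motif is defined by its position downstream of the
# PPT, not by cage content.

AROMATIC <- c("Y", "W", "F")

#' Extract and classify the chromodomain of an annotated element
#'
#' @param ann annotation bundle from [annotate_element()] (needs `orf`,
#'   `ppts`, `domains`, `element_seq`, `ltr3_start_local`).
#' @param panel reference panel (default bundled).
#' @return list of class `chromodomain_call`: `group` (I/II/CR/unclassified),
#'   `position_vs_ppt`, `peptide`, `cage_residues` (data.frame of position,
#'   residue, is_aromatic), `aa_start`, `aa_end` (protein coordinates,
#'   upstream case only).
#' @export
extract_chromodomain <- function(ann, panel = chromo_reference_panel()) {
  unclassified <- structure(list(group = "unclassified",
                                 position_vs_ppt = NA_character_,
                                 peptide = NULL, cage_residues = NULL,
                                 aa_start = NA_integer_, aa_end = NA_integer_),
                            class = "chromodomain_call")
  orf <- ann$orf
  if (is.null(orf)) return(unclassified)
  fppt <- Filter(function(p) p$role == "functional", ann$ppts)
  pep <- NULL; pos_vs_ppt <- NA_character_
  aa_start <- NA_integer_; aa_end <- NA_integer_

  if (isTRUE(orf$extends_into_3ltr) && length(fppt)) {
    # CRM layout: translate from the PPT end (rounded to the ORF frame) to
    # the stop codon inside the 3' LTR.  The layout alone carries the CR
    # call; a nonsense mutation shortening the window only blanks the cage.
    ppt_end <- fppt[[1L]]$end
    rel <- (ppt_end - orf$start) %% 3L
    s <- ppt_end + (3L - rel) %% 3L
    e <- orf$end - 3L
    pos_vs_ppt <- "downstream"
    pep <- if (e - s >= 30L) translate_nt(subseq_chr(ann$element_seq, s, e))
           else ""
  }
  if (identical(pos_vs_ppt, "downstream") && !nchar(pep %||% "")) {
    return(structure(list(group = "CR", position_vs_ppt = "downstream",
                          peptide = NULL, cage_residues = NULL,
                          aa_start = NA_integer_, aa_end = NA_integer_),
                     class = "chromodomain_call"))
  }
  if (is.null(pep)) {
    dom <- ann$domains
    if (!is.null(dom) && nrow(dom) && "INT_GPFY" %in% dom$name) {
      g <- dom[dom$name == "INT_GPFY", ][1L, ]
      prot <- orf$protein
      if (g$aa_end + 10L <= nchar(prot)) {
        aa_start <- g$aa_end + 1L
        aa_end <- nchar(prot)
        pep <- substr(prot, aa_start, aa_end)
        pos_vs_ppt <- "upstream"
      }
    }
  }
  if (is.null(pep) || !nchar(pep)) return(unclassified)

  al <- Biostrings::pairwiseAlignment(pep, panel$hp1,
                                      substitutionMatrix = blosum62(),
                                      gapOpening = 10, gapExtension = 0.5,
                                      type = "overlap")
  ac <- aligned_chars(al)
  subj_pos <- cumsum(ac$s != "-")
  cage <- vapply(panel$cage_columns, function(cc) {
    hit <- which(subj_pos == cc & ac$s != "-")
    if (!length(hit)) return(NA_character_)
    r <- ac$p[hit[1L]]
    if (r == "-") NA_character_ else r
  }, "")
  arom <- cage %in% AROMATIC
  cage_df <- data.frame(position = panel$cage_columns, residue = cage,
                        is_aromatic = arom)
  group <- if (identical(pos_vs_ppt, "downstream")) "CR"
    else if (any(is.na(cage))) "unclassified"
    else if (all(arom)) "I"
    else if (arom[2L] && !arom[1L] && !arom[3L]) "II"
    else "unclassified"
  structure(list(group = group, position_vs_ppt = pos_vs_ppt, peptide = pep,
                 cage_residues = cage_df, aa_start = aa_start,
                 aa_end = aa_end),
            class = "chromodomain_call")
}

#' Assign the chromoviral clade
#'
#' CRM is called whenever the chromodomain lies downstream of the PPT;
#' otherwise the element is assigned by nearest-reference vote on global
#' RT identity against the bundled clade exemplars.  Conflicting evidence is
#' recorded, never silently resolved.
#'
#' @param cd_call chromodomain call from [extract_chromodomain()] (may be
#'   NULL).
#' @param rt_protein RT peptide of the element (may be NULL).
#' @param panel reference panel.
#' @param threshold minimum RT identity for a nearest-reference assignment.
#' @return list of class `clade_call`: `clade`, `evidence`,
#'   `nearest_reference_id`, `rt_identity_to_nearest`, `conflict`.
#' @export
assign_clade <- function(cd_call, rt_protein, panel = chromo_reference_panel(),
                         threshold = 0.40) {
  if (is.null(panel$clades) || !length(panel$clades))
    stop_config("empty reference panel")
  ids <- NULL
  if (!is.null(rt_protein) && nchar(rt_protein)) {
    ids <- vapply(panel$clades, function(p)
      pairwise_identity(rt_protein, p$RT), 0)
  }
  nearest <- if (!is.null(ids)) names(ids)[which.max(ids)] else NA_character_
  best <- if (!is.null(ids)) max(ids) else NA_real_
  downstream <- !is.null(cd_call) && identical(cd_call$position_vs_ppt,
                                               "downstream")
  conflict <- NA_character_
  if (downstream) {
    evidence <- "cd_layout"
    if (!is.null(ids) && best >= threshold) {
      if (nearest == "CRM") evidence <- "both"
      else conflict <- sprintf("downstream CD but nearest RT is %s (%.2f)",
                               nearest, best)
    }
    clade <- "CRM"
  } else if (!is.null(ids) && best >= threshold) {
    clade <- nearest
    evidence <- "rt_similarity"
    if (!is.null(cd_call) && identical(cd_call$group, "II")) {
      if (clade == "CRM")
        conflict <- "group II chromodomain but nearest RT is CRM"
      else evidence <- "both"
    }
  } else {
    clade <- "unassigned"
    evidence <- if (!is.null(cd_call) && !is.na(cd_call$position_vs_ppt))
      "cd_layout" else NA_character_
  }
  structure(list(clade = clade, evidence = evidence,
                 nearest_reference_id = if (!is.na(nearest) && !is.null(ids))
                   paste0(nearest, "_RT") else NA_character_,
                 rt_identity_to_nearest = best, conflict = conflict),
            class = "clade_call")
}

#' Detect nuclear localization signals
#'
#' All matches of the motif P-x-(R|K)-K-x-K.
#'
#' @param protein_seq amino-acid string.
#' @return list of hits, each `list(aa_start, aa_end, match)`, in order.
#' @export
detect_nls <- function(protein_seq) {
  if (!nchar(protein_seq)) return(list())
  m <- gregexpr("P.[RK]K.K", protein_seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(list())
  lens <- attr(m, "match.length")
  lapply(seq_along(m), function(i)
    list(aa_start = as.integer(m[i]), aa_end = as.integer(m[i]) + lens[i] - 1L,
         match = substr(protein_seq, m[i], m[i] + lens[i] - 1L)))
}
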