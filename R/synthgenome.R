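# Synthetic chromovirus genome generator.
#
# Emits i.i.d.-background genomes with implanted LTR retrotransposons built
# from four clade templates (CRM, Tekay, Reina, Galadriel) and a full truth
# channel: every structural feature (LTRs, TSD, PBS, PPT(s), ORF, chromodomain)
# is recorded in genome coordinates (0-based, half-open).  Clade layout rules:
# CRM places the chromodomain downstream of the PPT with the gag-pol ORF
# extending into the 3' LTR; Tekay/Reina/Galadriel encode the chromodomain at
# the integrase C-terminus, upstream of the PPT.

#' Default PBS motif
#'
#' Reverse complement of the 3'-terminal 12 nt of the plant initiator
#' tRNA-Met; configurable per template.
#' @export
DEFAULT_PBS_MOTIF <- "TGGTATCAGAGC"

#' Clade template for element construction
#'
#' Describes the structural layout of one chromoviral clade.  Defaults give
#' element sizes and LTR lengths inside the observed ranges for Beta
#' chromoviruses (LTRs roughly 290-3000 nt, elements 5.2-11.6 kb); the
#' Galadriel default (631 nt LTRs, 4776 nt internal region, 6038 nt total)
#' mirrors the Beon1 reference element.
#'
#' @param clade one of "CRM", "Tekay", "Reina", "Galadriel".
#' @param ltr_length LTR length in nt (both copies identical at insertion).
#' @param internal_length length of the internal region (between the LTRs).
#' @param pbs_motif primer-binding-site motif planted next to the 5' LTR.
#' @param ppt_length polypurine-tract length, 7-14 purines.
#' @param has_ppt_a plant an additional internal purine run (PPT_a)
#'   overlapping the gag-pol stop codon (Bongo3-like layout).
#' @return object of class `clade_template`.
#' @export
clade_template <- function(clade = c("CRM", "Tekay", "Reina", "Galadriel"),
                           ltr_length = NULL, internal_length = NULL,
                           pbs_motif = DEFAULT_PBS_MOTIF,
                           ppt_length = NULL, has_ppt_a = FALSE) {
  clade <- match.arg(clade)
  defaults <- list(
    CRM       = list(ltr = 900L,  int = 4200L, ppt = 13L),
    Tekay     = list(ltr = 2600L, int = 5200L, ppt = 12L),
    Reina     = list(ltr = 430L,  int = 4900L, ppt = 12L),
    Galadriel = list(ltr = 631L,  int = 4776L, ppt = 12L))[[clade]]
  ltr_length <- as.integer(ltr_length %||% defaults$ltr)
  internal_length <- as.integer(internal_length %||% defaults$int)
  ppt_length <- as.integer(ppt_length %||% defaults$ppt)
  if (ppt_length < 7L || ppt_length > 14L)
    stop_config("ppt_length must be in [7, 14], got %d", ppt_length)
  if (ltr_length <= 0L || internal_length <= 0L)
    stop_config("ltr_length and internal_length must be positive")
  crm <- clade == "CRM"
  structure(list(
    clade_name = clade,
    ltr_length = ltr_length,
    internal_length = internal_length,
    cd_relative_to_ppt = if (crm) "downstream" else "upstream",
    orf_into_3ltr = crm,
    cd_group = if (crm) "CR" else "II",
    domain_cassette = c("GAG_ZF", "PR", "RT", "RH",
                        "INT_ZF_HHCC", "INT_DD35E", "INT_GPFY", "CD"),
    pbs_motif = toupper(pbs_motif),
    ppt_length = ppt_length,
    has_ppt_a = isTRUE(has_ppt_a)
  ), class = "clade_template")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specification of one element insertion
#'
#' @param template a [clade_template()].
#' @param position 0-based offset into the background sequence.
#' @param tsd target-site duplication string (NULL = drawn at generation
#'   time); its length must equal the generator's `tsd_length`.
#' @param ltr_divergence per-site substitution probability applied
#'   independently to the 3' LTR copy, in \[0, 1).
#' @param truncation one of "none", "5ltr_partial", "3ltr_partial",
#'   "internal_deletion".
#' @param truncation_extent nt removed by the truncation.
#' @param orientation "forward" or "reverse".
#' @param disrupt_orf inject a premature in-frame stop codon mid-ORF.
#' @param pbs_offset distance (0-3 nt) between the 5' LTR and the PBS.
#' @return object of class `insertion_spec`.
#' @export
insertion_spec <- function(template, position, tsd = NULL,
                           ltr_divergence = 0,
                           truncation = c("none", "5ltr_partial",
                                          "3ltr_partial", "internal_deletion"),
                           truncation_extent = 0L,
                           orientation = c("forward", "reverse"),
                           disrupt_orf = FALSE, pbs_offset = 1L) {
  truncation <- match.arg(truncation)
  orientation <- match.arg(orientation)
  if (!inherits(template, "clade_template")) stop_config("template must be a clade_template")
  if (ltr_divergence < 0 || ltr_divergence >= 1)
    stop_config("ltr_divergence must be in [0, 1)")
  if (pbs_offset < 0L || pbs_offset > 3L)
    stop_config("pbs_offset must be within 0-3 nt of the 5' LTR")
  if (truncation != "none" && truncation_extent <= 0L)
    stop_config("truncation requires a positive extent")
  structure(list(template = template, position = as.integer(position),
                 tsd = if (is.null(tsd)) NULL else toupper(tsd),
                 ltr_divergence = ltr_divergence,
                 truncation = truncation,
                 truncation_extent = as.integer(truncation_extent),
                 orientation = orientation,
                 disrupt_orf = isTRUE(disrupt_orf),
                 pbs_offset = as.integer(pbs_offset)),
            class = "insertion_spec")
}

#' Observed divergence between two equal-length LTR copies
#'
#' Truth-side check: fraction of differing sites by direct comparison.
#'
#' @param ltr5,ltr3 nucleotide strings of equal length.
#' @return fraction of differing sites.
#' @export
realized_divergence <- function(ltr5, ltr3) {
  if (nchar(ltr5) != nchar(ltr3))
    stop_input("realized_divergence requires equal-length LTR copies")
  hamming(ltr5, ltr3) / nchar(ltr5)
}

# ---- element assembly -------------------------------------------------------

random_peptide <- function(n) {
  if (n <= 0) return("")
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

purine_run <- function(n) paste(sample(c("A", "G"), n, replace = TRUE), collapse = "")

mutate_sites <- function(seq, rate) {
  v <- seq_chars(seq)
  hit <- which(runif(length(v)) < rate)
  if (length(hit))
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(DNA, b), 1L), "")
  list(seq = paste(v, collapse = ""), n_mut = length(hit))
}

# Build one intact forward element from a template.  Returns the element
# string plus element-local feature coordinates (0-based half-open).
build_element <- function(tpl, pbs_offset = 1L, panel = chromo_reference_panel()) {
  pep <- panel$clades[[tpl$clade_name]]
  link <- function() random_peptide(8L)
  crm <- tpl$clade_name == "CRM"
  internal <- tpl$internal_length
  L <- tpl$ltr_length
  pbs <- tpl$pbs_motif

  cassette <- paste0(pep$GAG_ZF, link(), pep$PR, link(), pep$RT, link(),
                     pep$RH, link(), pep$INT)

  if (crm) {
    cd_nt <- reverse_translate(pep$CD)
    # internal = pbs_offset + |pbs| + utr5 + orf_nt_main + ppt
    overhead <- pbs_offset + nchar(pbs) + tpl$ppt_length
    utr5_target <- max(60L, round(0.08 * internal))
    fixed_aa <- 1L + nchar(cassette)
    extra_aa <- ((internal - overhead - utr5_target) %/% 3L) - fixed_aa
    if (extra_aa < 0L)
      stop_config("internal_length %d too small for the %s domain cassette",
                  internal, tpl$clade_name)
    orf_pep <- paste0("M", pep$GAG_ZF, random_peptide(extra_aa), link(),
                      pep$PR, link(), pep$RT, link(), pep$RH, link(), pep$INT)
    orf_nt_main <- reverse_translate(orf_pep)
    utr5 <- internal - overhead - nchar(orf_nt_main)
    ltr_fill <- L - 2L - nchar(cd_nt) - 3L - 2L
    if (ltr_fill < 0L)
      stop_config("CRM ltr_length %d cannot host the chromodomain", L)
    # LTR carries the CR chromodomain just after its TG terminus
    ltr <- paste0("TG", cd_nt, "TAA", random_dna(ltr_fill), "CA")
    utr5_seq <- random_dna(utr5)
    ppt <- purine_run(tpl$ppt_length)
    elem <- paste0(ltr, random_dna(pbs_offset), pbs, utr5_seq,
                   orf_nt_main, ppt, ltr)
    ltr5_end <- L
    pbs_start <- L + pbs_offset
    orf_start <- pbs_start + nchar(pbs) + utr5
    ppt_start <- orf_start + nchar(orf_nt_main)
    ltr3_start <- ppt_start + tpl$ppt_length
    orf_end <- ltr3_start + 2L + nchar(cd_nt) + 3L  # through the LTR-internal stop
    cd_start <- ltr3_start + 2L
    feats <- list(ltr5 = c(0L, L), pbs = c(pbs_start, pbs_start + nchar(pbs)),
                  orf = c(orf_start, orf_end),
                  ppt = c(ppt_start, ltr3_start), ppt_a = NULL,
                  cd = c(cd_start, cd_start + nchar(cd_nt)),
                  ltr3 = c(ltr3_start, ltr3_start + L))
  } else {
    ppt_a_len <- if (tpl$has_ppt_a) 10L else 0L
    overhead <- pbs_offset + nchar(pbs) + tpl$ppt_length + ppt_a_len
    utr_target <- max(120L, round(0.10 * internal))
    fixed_aa <- 1L + nchar(cassette) + nchar(pep$CD)
    extra_aa <- ((internal - overhead - utr_target - 3L) %/% 3L) - fixed_aa
    if (extra_aa < 0L)
      stop_config("internal_length %d too small for the %s domain cassette",
                  internal, tpl$clade_name)
    orf_pep <- paste0("M", pep$GAG_ZF, random_peptide(extra_aa), link(),
                      pep$PR, link(), pep$RT, link(), pep$RH, link(),
                      pep$INT, pep$CD)
    orf_nt <- paste0(reverse_translate(orf_pep), "TAA")
    utr_total <- internal - overhead - nchar(orf_nt)
    utr3 <- max(10L, utr_total %/% 2L)
    utr5 <- utr_total - utr3
    if (utr5 < 0L)
      stop_config("internal_length %d infeasible for %s", internal, tpl$clade_name)
    ppt_a <- if (tpl$has_ppt_a) purine_run(ppt_a_len) else ""
    # pyrimidine guards keep planted purine runs maximal and exactly placed
    utr3_seq <- random_dna(utr3)
    utr3_seq <- paste0("C", substr(utr3_seq, 2L, utr3 - 1L), "T")
    ltr <- paste0("TG", random_dna(L - 4L), "CA")
    elem <- paste0(ltr, random_dna(pbs_offset), pbs, random_dna(utr5),
                   orf_nt, ppt_a, utr3_seq, purine_run(tpl$ppt_length), ltr)
    ltr5_end <- L
    pbs_start <- L + pbs_offset
    orf_start <- pbs_start + nchar(pbs) + utr5
    orf_end <- orf_start + nchar(orf_nt)
    ppt_a_coord <- if (tpl$has_ppt_a) c(orf_end, orf_end + ppt_a_len) else NULL
    ppt_start <- orf_end + ppt_a_len + utr3
    ltr3_start <- ppt_start + tpl$ppt_length
    cd_nt_len <- 3L * nchar(pep$CD)
    cd_end <- orf_end - 3L
    feats <- list(ltr5 = c(0L, L), pbs = c(pbs_start, pbs_start + nchar(pbs)),
                  orf = c(orf_start, orf_end),
                  ppt = c(ppt_start, ltr3_start), ppt_a = ppt_a_coord,
                  cd = c(cd_end - cd_nt_len, cd_end),
                  ltr3 = c(ltr3_start, ltr3_start + L))
  }
  stopifnot(nchar(elem) == 2L * L + internal)
  list(seq = elem, feats = feats, orf_pep_len = nchar(orf_pep))
}

# Apply divergence, optional ORF disruption and truncation to a built element.
finish_element <- function(built, spec) {
  elem <- built$seq
  f <- built$feats
  L <- f$ltr3[2] - f$ltr3[1]
  ltr5_seq <- subseq_chr(elem, f$ltr5[1], f$ltr5[2])
  ltr3 <- subseq_chr(elem, f$ltr3[1], f$ltr3[2])
  mut <- mutate_sites(ltr3, spec$ltr_divergence)
  elem <- paste0(subseq_chr(elem, 0L, f$ltr3[1]), mut$seq)
  realized <- realized_divergence(ltr5_seq, mut$seq)

  if (spec$disrupt_orf) {
    # premature stop mid-ORF, codon-aligned
    mid_codon <- (f$orf[2] - f$orf[1]) %/% 6L
    at <- f$orf[1] + 3L * mid_codon
    elem <- paste0(subseq_chr(elem, 0L, at), "TAA",
                   subseq_chr(elem, at + 3L, nchar(elem)))
  }

  shift_feats <- function(f, cut_start, cut_end) {
    # remove [cut_start, cut_end) and clip/shift features
    w <- cut_end - cut_start
    lapply(f, function(co) {
      if (is.null(co)) return(NULL)
      a <- co[1]; b <- co[2]
      a2 <- if (a >= cut_end) a - w else min(a, cut_start)
      b2 <- if (b >= cut_end) b - w else min(b, cut_start)
      if (b2 <= a2) NULL else c(a2, b2)
    })
  }
  if (spec$truncation != "none") {
    x <- spec$truncation_extent
    n <- nchar(elem)
    cut <- switch(spec$truncation,
      "5ltr_partial" = c(0L, min(x, L - 1L)),
      "3ltr_partial" = c(n - min(x, L - 1L), n),
      "internal_deletion" = {
        mid <- (f$ltr5[2] + f$ltr3[1]) %/% 2L
        c(mid - x %/% 2L, mid - x %/% 2L + x)
      })
    elem <- paste0(subseq_chr(elem, 0L, cut[1]), subseq_chr(elem, cut[2], nchar(elem)))
    f <- shift_feats(f, cut[1], cut[2])
  }
  list(seq = elem, feats = f, realized_divergence = realized)
}

# ---- genome assembly ---------------------------------------------------------

#' Generate a synthetic genome with implanted chromoviruses
#'
#' Splices each requested element (flanked by two identical copies of its
#' TSD) into an i.i.d. nucleotide background, and returns the genome together
#' with a truth table recording every realized feature in genome coordinates
#' (0-based, half-open).  Identical `(config, seed)` pairs give byte-identical
#' output.
#'
#' @param config list with fields `bg_length`, `gc` (default 0.36),
#'   `insertions` (list of [insertion_spec()]), `tsd_length` (default 5),
#'   `min_spacing` (default 200 nt between insertion points),
#'   `decoy_repeats` (count of tandem low-complexity decoys, default 0),
#'   `seq_id` (default "synthgenome").
#' @param seed integer seed; required for reproducibility.
#' @return list with `genome` (named character vector of length 1) and
#'   `truth` (data.frame, one row per implanted element).
#' @export
generate_genome <- function(config, seed) {
  if (missing(seed) || is.null(seed)) stop_config("generate_genome requires a seed")
  cfg <- config
  cfg$gc <- cfg$gc %||% 0.36
  cfg$tsd_length <- as.integer(cfg$tsd_length %||% 5L)
  cfg$min_spacing <- as.integer(cfg$min_spacing %||% 200L)
  cfg$decoy_repeats <- as.integer(cfg$decoy_repeats %||% 0L)
  cfg$seq_id <- cfg$seq_id %||% "synthgenome"
  cfg$insertions <- cfg$insertions %||% list()
  if (is.null(cfg$bg_length)) stop_config("config$bg_length is required")
  bg_len <- as.integer(cfg$bg_length)

  specs <- cfg$insertions
  if (length(specs)) {
    if (!all(vapply(specs, inherits, TRUE, "insertion_spec")))
      stop_config("config$insertions must be insertion_spec objects")
    pos <- vapply(specs, function(s) s$position, 1L)
    o <- order(pos)
    specs <- specs[o]; pos <- pos[o]
    if (any(pos < cfg$tsd_length) || any(pos > bg_len - cfg$tsd_length))
      stop_config("insertion position outside background (margins = tsd_length)")
    if (length(pos) > 1L && any(diff(pos) < cfg$min_spacing))
      stop_config("insertion positions closer than min_spacing = %d", cfg$min_spacing)
    total_elem <- sum(vapply(specs, function(s)
      2L * s$template$ltr_length + s$template$internal_length, 1L))
    if (bg_len < total_elem + (length(specs) + 1L) * cfg$min_spacing)
      stop_config(paste("background length %d below the inserted element",
                        "total %d plus spacing margins"), bg_len, total_elem)
  }

  with_seed(seed, {
    bg <- random_dna(bg_len, cfg$gc)
    if (cfg$decoy_repeats > 0L) {
      for (i in seq_len(cfg$decoy_repeats)) {
        unit <- random_dna(60L, cfg$gc)
        at <- sample.int(bg_len - 1L, 1L)
        bg <- paste0(subseq_chr(bg, 0L, at),
                     strrep(unit, 6L),
                     subseq_chr(bg, at, nchar(bg)))
      }
      bg_len <- nchar(bg)
    }

    pieces <- character(0)
    truth <- list()
    prev <- 0L
    out_off <- 0L
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      tsd <- sp$tsd %||% paste(sample(DNA, cfg$tsd_length, TRUE), collapse = "")
      if (nchar(tsd) != cfg$tsd_length)
        stop_config("tsd length %d != configured tsd_length %d",
                    nchar(tsd), cfg$tsd_length)
      built <- build_element(sp$template, pbs_offset = sp$pbs_offset)
      fin <- finish_element(built, sp)
      elem <- fin$seq
      feats <- fin$feats
      n <- nchar(elem)
      if (sp$orientation == "reverse") {
        elem <- revcomp(elem)
        feats <- lapply(feats, function(co)
          if (is.null(co)) NULL else c(n - co[2], n - co[1]))
        # after revcomp the 5' LTR of the element sense strand is rightmost;
        # keep genome-ordered naming: swap so ltr5 is the left feature
        tmp <- feats$ltr5; feats$ltr5 <- feats$ltr3; feats$ltr3 <- tmp
      }
      chunk_bg <- subseq_chr(bg, prev, sp$position)
      pieces <- c(pieces, chunk_bg, tsd, elem, tsd)
      out_off <- out_off + nchar(chunk_bg)
      tsd_left <- out_off
      est <- out_off + cfg$tsd_length       # element start in genome space
      g <- function(co) if (is.null(co)) c(NA_integer_, NA_integer_) else est + co
      truth[[i]] <- data.frame(
        element_id = sprintf("%s_elem%02d", sp$template$clade_name, i),
        clade = sp$template$clade_name,
        seq_id = cfg$seq_id,
        start = est, end = est + n,
        tsd = tsd, tsd_left_start = tsd_left, tsd_right_start = est + n,
        ltr5_start = g(feats$ltr5)[1], ltr5_end = g(feats$ltr5)[2],
        ltr3_start = g(feats$ltr3)[1], ltr3_end = g(feats$ltr3)[2],
        pbs_start = g(feats$pbs)[1], pbs_end = g(feats$pbs)[2],
        ppt_start = g(feats$ppt)[1], ppt_end = g(feats$ppt)[2],
        ppt_a_start = g(feats$ppt_a)[1], ppt_a_end = g(feats$ppt_a)[2],
        orf_start = g(feats$orf)[1], orf_end = g(feats$orf)[2],
        cd_start = g(feats$cd)[1], cd_end = g(feats$cd)[2],
        orientation = sp$orientation,
        requested_divergence = sp$ltr_divergence,
        realized_divergence = fin$realized_divergence,
        truncation = sp$truncation,
        truncation_extent = sp$truncation_extent,
        disrupted = sp$disrupt_orf,
        ltr_length = sp$template$ltr_length,
        internal_length = sp$template$internal_length,
        stringsAsFactors = FALSE)
      out_off <- est + n + cfg$tsd_length
      prev <- sp$position
    }
    pieces <- c(pieces, subseq_chr(bg, prev, nchar(bg)))
    genome <- setNames(paste(pieces, collapse = ""), cfg$seq_id)
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(element_id = character(0))
    list(genome = genome, truth = truth, seed = seed, config = cfg)
  })
}

#' Convenience simulator: n elements across the four clades
#'
#' Positions are laid out on a regular grid of the background with the
#' requested spacing; divergence values are drawn uniformly from
#' `divergence_range`.
#'
#' @param n_elements number of implanted elements.
#' @param clades clade names recycled across elements.
#' @param divergence_range range for per-element LTR divergence.
#' @param spacing background nt between insertion points.
#' @param seed integer seed.
#' @param ... passed to [insertion_spec()] (e.g. `orientation`).
#' @return as [generate_genome()].
#' @export
simulate_chromovirus_genome <- function(n_elements = 50,
                                        clades = c("CRM", "Tekay", "Reina",
                                                   "Galadriel"),
                                        divergence_range = c(0, 0.05),
                                        spacing = 1000L, seed = 1L, ...) {
  clades <- rep_len(clades, n_elements)
  divs <- with_seed(seed + 1L,
                    runif(n_elements, divergence_range[1], divergence_range[2]))
  specs <- lapply(seq_len(n_elements), function(i)
    insertion_spec(clade_template(clades[i]), position = i * spacing,
                   ltr_divergence = divs[i], ...))
  total_elem <- sum(vapply(specs, function(s)
    2L * s$template$ltr_length + s$template$internal_length, 1L))
  cfg <- list(bg_length = total_elem + (n_elements + 1L) * spacing,
              insertions = specs)
  generate_genome(cfg, seed = seed)
}

# ---- truth-channel writers ---------------------------------------------------

#' Write the truth table as GFF3 (1-based inclusive)
#'
#' @param truth truth data.frame from [generate_genome()].
#' @param path output file.
#' @export
write_truth_gff3 <- function(truth, path) {
  lines <- "##gff-version 3"
  gff <- function(seqid, type, s, e, id, parent = NULL) {
    attr <- paste0("ID=", id, if (!is.null(parent)) paste0(";Parent=", parent))
    sprintf("%s\tchromoscan_synth\t%s\t%d\t%d\t.\t+\t.\t%s",
            seqid, type, s + 1L, e, attr)
  }
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    id <- r$element_id
    lines <- c(lines,
      gff(r$seq_id, "LTR_retrotransposon", r$start, r$end, id),
      gff(r$seq_id, "target_site_duplication", r$tsd_left_start,
          r$tsd_left_start + nchar(r$tsd), paste0(id, "_tsdL"), id),
      gff(r$seq_id, "target_site_duplication", r$tsd_right_start,
          r$tsd_right_start + nchar(r$tsd), paste0(id, "_tsdR"), id))
    feat <- list(long_terminal_repeat = c(r$ltr5_start, r$ltr5_end),
                 long_terminal_repeat2 = c(r$ltr3_start, r$ltr3_end),
                 primer_binding_site = c(r$pbs_start, r$pbs_end),
                 RR_tract = c(r$ppt_start, r$ppt_end),
                 RR_tract_a = c(r$ppt_a_start, r$ppt_a_end),
                 CDS = c(r$orf_start, r$orf_end))
    for (nm in names(feat)) {
      co <- feat[[nm]]
      if (any(is.na(co))) next
      type <- sub("2$|_a$", "", nm)
      lines <- c(lines, gff(r$seq_id, type, co[1], co[2],
                            paste0(id, "_", nm), id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the truth table as TSV
#' @param truth truth data.frame.
#' @param path output file.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
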