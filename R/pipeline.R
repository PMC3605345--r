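# Pipeline orchestration: generate/load -> detect -> polish -> annotate ->
# classify -> cluster -> date -> report.  All randomness flows from the
# single top-level seed; identical (config, seed) runs give identical
# artifacts.

#' Default pipeline configuration
#'
#' @return list of defaults; every field can be overridden in the config
#'   passed to [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(genome_fasta = NULL, synth = NULL, seed = 1L, outdir = NULL,
       ltrfind = list(), tsd_length = 5L, max_tsd_mismatch = 0L,
       pbs_motif = DEFAULT_PBS_MOTIF, family_threshold = 0.80,
       rate = DEFAULT_SUBSTITUTION_RATE, verbose = FALSE)
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file.
#' @return config list merged over the defaults.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_pipeline_config(), cfg)
}

#' @rdname read_pipeline_config
#' @param config config list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

log_msg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[chromoscan] ", fmt), ...))
}

#' Run the full discovery-and-characterization pipeline
#'
#' @param config list (see [default_pipeline_config()]): either
#'   `genome_fasta` (path) or `synth` (arguments to
#'   [simulate_chromovirus_genome()]) must be given.  When `outdir` is set,
#'   all artifacts (TSV/GFF3/JSON, plus FASTA and truth tables for synthetic
#'   runs) are written there.
#' @return run report (list): `n_candidates`, `completeness_counts`,
#'   `clade_counts`, `clade_fractions`, `elements` (data.frame),
#'   `age_table`, `families`, `annotations` (list of bundles), `truth`
#'   (synthetic runs), `provenance`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (is.null(cfg$genome_fasta) && is.null(cfg$synth))
    stop_config("config needs either genome_fasta or synth")
  truth <- NULL
  if (!is.null(cfg$genome_fasta)) {
    genome <- read_fasta(cfg$genome_fasta)
  } else {
    sim <- do.call(simulate_chromovirus_genome,
                   utils::modifyList(cfg$synth, list(seed = cfg$seed)))
    genome <- sim$genome
    truth <- sim$truth
  }
  log_msg(cfg$verbose, "genome: %d sequence(s), %d nt", length(genome),
          sum(nchar(genome)))

  cands <- find_ltr_pairs(genome, cfg$ltrfind)
  log_msg(cfg$verbose, "%d LTR-pair candidate(s)", nrow(cands))

  anns <- list()
  rows <- list()
  for (i in seq_len(nrow(cands))) {
    res <- tryCatch({
      cand <- refine_boundaries(genome[[cands$seq_id[i]]], as.list(cands[i, ]),
                                tsd_length = cfg$tsd_length)
      annotate_element(genome[[cand$seq_id]], cand,
                       pbs_motif = cfg$pbs_motif,
                       tsd_length = cfg$tsd_length,
                       max_tsd_mismatch = cfg$max_tsd_mismatch)
    }, error = function(e) {
      if (inherits(e, "chromoscan_config_error")) stop(e)
      message(sprintf("[chromoscan] candidate %d failed: %s", i,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    anns[[length(anns) + 1L]] <- res
    cand <- res$cand
    name <- sprintf("%s_%d", cand$seq_id, cand$ltr5_start)
    l5 <- res$ltr5_seq; l3 <- res$ltr3_seq
    age <- NULL
    if (nchar(l5) >= 50L && nchar(l3) >= 50L) {
      age <- tryCatch({
        dv <- ltr_divergence(l5, l3)
        estimate_age(dv$K, cfg$rate, dv$aligned_span, dv$partial_ltr)
      }, error = function(e) NULL)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = name, seq_id = cand$seq_id,
      start = cand$ltr5_start, end = cand$ltr3_end,
      total_length = cand$ltr3_end - cand$ltr5_start,
      ltr5_length = cand$ltr5_end - cand$ltr5_start,
      ltr3_length = cand$ltr3_end - cand$ltr3_start,
      strand = res$strand,
      tsd = if (isTRUE(res$tsd$present)) res$tsd$tsd_sequence else NA_character_,
      ltr_identity = cand$ltr_identity,
      divergence_pct = if (!is.null(age)) 100 * age$K else NA_real_,
      age_mya = if (!is.null(age)) age$t_mya else NA_real_,
      partial_ltr = if (!is.null(age)) age$partial_ltr else NA,
      completeness = res$completeness,
      clade = res$clade_call$clade,
      cd_group = res$cd_call$group,
      stringsAsFactors = FALSE)
  }
  elements <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(0), completeness = character(0),
               clade = character(0))

  full <- elements$completeness == "full_length"
  fams <- setNames(character(0), character(0))
  if (any(full)) {
    ltrs <- setNames(
      vapply(anns[full], function(a) a$ltr5_seq, ""),
      elements$name[full])
    fams <- cluster_families(ltrs, cfg$family_threshold)
  }
  elements[["family"]] <- rep(NA_character_, nrow(elements))
  if (length(fams)) elements$family[match(names(fams), elements$name)] <- fams

  comp <- table(factor(elements$completeness,
                       levels = c("full_length", "incomplete", "degenerate")))
  clades <- table(factor(elements$clade,
                         levels = c("CRM", "Tekay", "Reina", "Galadriel",
                                    "unassigned")))
  report <- list(
    n_candidates = nrow(cands),
    completeness_counts = as.list(comp),
    clade_counts = as.list(clades),
    clade_fractions = as.list(if (sum(clades)) clades / sum(clades) else clades),
    elements = elements,
    age_table = elements[full, intersect(c("name", "clade", "total_length",
                                           "ltr5_length", "ltr3_length", "tsd",
                                           "divergence_pct", "age_mya",
                                           "partial_ltr"), names(elements))],
    families = fams,
    annotations = anns,
    truth = truth,
    provenance = list(
      package = "chromoscan",
      version = as.character(utils::packageVersion("chromoscan")),
      seed = cfg$seed,
      config_hash = djb2_hash(jsonlite::toJSON(
        cfg[setdiff(names(cfg), c("verbose", "outdir"))],
        auto_unbox = TRUE, digits = NA))))

  if (!is.null(cfg$outdir)) write_pipeline_outputs(report, genome, cfg)
  report
}

write_pipeline_outputs <- function(report, genome, cfg) {
  out <- cfg$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$truth)) {
    write_fasta(genome, file.path(out, "genome.fasta"))
    write_truth_tsv(report$truth, file.path(out, "truth.tsv"))
    write_truth_gff3(report$truth, file.path(out, "truth.gff3"))
  }
  write.table(report$elements, file.path(out, "elements.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  emit_table1_report(report$elements[report$elements$completeness ==
                                       "full_length", , drop = FALSE],
                     file.path(out, "full_length_report.tsv"))
  write_annotation_gff3(report$annotations, file.path(out, "annotations.gff3"))
  summary <- report[c("n_candidates", "completeness_counts", "clade_counts",
                      "clade_fractions", "provenance")]
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Per-element report in the printed-table style
#'
#' One row per full-length element: name, clade, total length, LTR lengths,
#' TSD, LTR divergence (percent, 2 decimals) and age in Mya (3 significant
#' digits; identical LTRs print "0 (identical LTRs)"; partial-LTR estimates
#' are parenthesized).
#'
#' @param elements element data.frame (see [run_pipeline()] `$elements`).
#' @param path optional TSV output path.
#' @return formatted data.frame (invisibly when `path` is given).
#' @export
emit_table1_report <- function(elements, path = NULL) {
  if (!nrow(elements)) {
    out <- data.frame(name = character(0), clade = character(0),
                      total_length = integer(0), ltr_5_3 = character(0),
                      tsd = character(0), divergence_pct = character(0),
                      age_mya = character(0))
    if (!is.null(path)) {
      write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
      return(invisible(out))
    }
    return(out)
  }
  fmt_age <- function(div, age, partial) {
    if (is.na(age)) return(NA_character_)
    if (div == 0) return("0 (identical LTRs)")
    a <- as.character(signif(age, 3))
    if (isTRUE(partial)) paste0("(", a, ")") else a
  }
  out <- data.frame(
    name = elements$name, clade = elements$clade,
    total_length = elements$total_length,
    ltr_5_3 = paste0(elements$ltr5_length, "/", elements$ltr3_length),
    tsd = elements$tsd,
    divergence_pct = sprintf("%.2f", elements$divergence_pct),
    age_mya = mapply(fmt_age, elements$divergence_pct, elements$age_mya,
                     elements$partial_ltr),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Write annotation bundles as GFF3 (1-based inclusive)
#'
#' @param anns list of annotation bundles from [annotate_element()].
#' @param path output file.
#' @export
write_annotation_gff3 <- function(anns, path) {
  lines <- "##gff-version 3"
  for (ann in anns) {
    cand <- ann$cand
    es <- cand$ltr5_start
    n <- nchar(ann$element_seq)
    loc <- function(co) {
      # element-local (sense) -> genome forward coordinates
      if (ann$strand == "+") es + co else es + c(n - co[2], n - co[1])
    }
    id <- sprintf("%s_%d", cand$seq_id, es)
    row <- function(type, s, e, rid, score = ".") sprintf(
      "%s\tchromoscan\t%s\t%d\t%d\t%s\t%s\t.\tID=%s;Parent=%s",
      cand$seq_id, type, s + 1L, e, score, ann$strand, rid, id)
    lines <- c(lines, sprintf(
      "%s\tchromoscan\tLTR_retrotransposon\t%d\t%d\t.\t%s\t.\tID=%s;completeness=%s;clade=%s",
      cand$seq_id, es + 1L, cand$ltr3_end, ann$strand, id,
      ann$completeness, ann$clade_call$clade))
    l5 <- loc(c(0L, ann$ltr5_end_local)); l3 <- loc(c(ann$ltr3_start_local, n))
    lines <- c(lines, row("long_terminal_repeat", l5[1], l5[2], paste0(id, "_ltrA")),
               row("long_terminal_repeat", l3[1], l3[2], paste0(id, "_ltrB")))
    if (isTRUE(ann$tsd$present)) {
      lines <- c(lines,
        row("target_site_duplication", ann$tsd$left_start,
            ann$tsd$left_start + ann$tsd$length, paste0(id, "_tsdL")),
        row("target_site_duplication", ann$tsd$right_start,
            ann$tsd$right_start + ann$tsd$length, paste0(id, "_tsdR")))
    }
    if (!is.null(ann$pbs)) {
      co <- loc(c(ann$pbs$start, ann$pbs$end))
      lines <- c(lines, row("primer_binding_site", co[1], co[2],
                            paste0(id, "_pbs")))
    }
    for (k in seq_along(ann$ppts)) {
      co <- loc(c(ann$ppts[[k]]$start, ann$ppts[[k]]$end))
      lines <- c(lines, row("RR_tract", co[1], co[2],
                            sprintf("%s_ppt%d", id, k)))
    }
    if (!is.null(ann$orf)) {
      co <- loc(c(ann$orf$start, ann$orf$end))
      lines <- c(lines, row("CDS", co[1], co[2], paste0(id, "_orf")))
    }
    if (!is.null(ann$domains) && nrow(ann$domains)) {
      orf0 <- ann$orf$start
      for (k in seq_len(nrow(ann$domains))) {
        dmn <- ann$domains[k, ]
        co <- loc(c(orf0 + 3L * (dmn$aa_start - 1L), orf0 + 3L * dmn$aa_end))
        lines <- c(lines, row("polypeptide_domain", co[1], co[2],
                              sprintf("%s_%s", id, dmn$name)))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
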