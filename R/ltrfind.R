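# De novo LTR-pair detection by genomic self-comparison: exact k-mer seeds
# shared between two windows at element-compatible distance are chained along
# diagonals, extended ungapped (X-drop), validated by a global alignment of
# the two LTR windows, and finally polished against the flanking target-site
# duplication.  Coordinates are 0-based, half-open throughout.

default_ltrfind_params <- function() {
  list(k = 13L, min_ltr = 100L, max_ltr = 3500L,
       min_element = 4000L, max_element = 13000L, min_identity = 0.80,
       chain_gap = 400L, xdrop = 7L, max_kmer_occ = 50L)
}

#' Find candidate LTR pairs in genomic sequence
#'
#' @param seqs named character vector of contigs (or a DNAStringSet).
#' @param params list overriding [default_ltrfind_params()]: `k` (seed
#'   length, 8-32), `min_ltr`/`max_ltr`, `min_element`/`max_element`,
#'   `min_identity`, `chain_gap`, `xdrop`, `max_kmer_occ`.
#' @return data.frame of candidates, one row each: `seq_id`, `ltr5_start`,
#'   `ltr5_end`, `ltr3_start`, `ltr3_end` (0-based half-open),
#'   `ltr_identity`, `strand`, `partial`; sorted by (seq_id, ltr5_start).
#' @export
find_ltr_pairs <- function(seqs, params = list()) {
  p <- utils::modifyList(default_ltrfind_params(), params)
  if (p$k < 8L || p$k > 32L) stop_config("seed length k must be in [8, 32]")
  for (nm in c("ltr", "element"))
    if (p[[paste0("min_", nm)]] > p[[paste0("max_", nm)]])
      stop_config("degenerate params: min_%s > max_%s", nm, nm)
  seqs <- as_seq_set(seqs)
  out <- lapply(names(seqs), function(id) {
    cands <- find_ltr_pairs_one(seqs[[id]], p)
    if (nrow(cands)) cands$seq_id <- id else cands <- empty_candidates()
    cands
  })
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res)) return(empty_candidates())
  res <- res[order(res$seq_id, res$ltr5_start), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("seq_id", setdiff(names(res), "seq_id"))]
}

empty_candidates <- function() {
  data.frame(seq_id = character(0), ltr5_start = integer(0),
             ltr5_end = integer(0), ltr3_start = integer(0),
             ltr3_end = integer(0), ltr_identity = numeric(0),
             strand = character(0), partial = logical(0),
             tsd_refined = logical(0))
}

find_ltr_pairs_one <- function(seq, p) {
  n <- nchar(seq)
  if (n < p$min_element) return(empty_candidates()[, -1])
  k <- p$k
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE)
  dt <- data.table::data.table(kmer = kmers[keep], pos = starts[keep])
  occ <- dt[, .N, by = "kmer"]
  dt <- dt[occ[occ$N <= p$max_kmer_occ & occ$N >= 2L], on = "kmer",
           nomatch = NULL]
  if (!nrow(dt)) return(empty_candidates()[, -1])
  dmin <- max(p$min_element - p$max_ltr, k)
  dmax <- p$max_element - k
  pairs <- dt[dt, on = "kmer", allow.cartesian = TRUE]
  pairs <- pairs[, list(pos = pos, d = i.pos - pos)]
  pairs <- pairs[pairs$d >= dmin & pairs$d <= dmax]
  if (!nrow(pairs)) return(empty_candidates()[, -1])
  data.table::setorderv(pairs, c("d", "pos"))

  # chain seeds along each diagonal, splitting at large positional gaps
  pairs[, `:=`(chain = cumsum(c(1L, diff(pos) > p$chain_gap | diff(d) != 0L)))]
  chains <- pairs[, list(d = d[1L], s = min(pos), e = max(pos) + k - 1L,
                         nseed = .N), by = "chain"]

  # merge chains on nearby diagonals with overlapping spans (indel slack)
  chains <- as.data.frame(chains)[order(chains$s), , drop = FALSE]
  merged <- list()
  for (i in seq_len(nrow(chains))) {
    ch <- chains[i, ]
    hit <- FALSE
    for (j in seq_along(merged)) {
      m <- merged[[j]]
      if (abs(ch$d - m$d) <= 25L && ch$s <= m$e + p$chain_gap && ch$e >= m$s) {
        merged[[j]] <- list(d = if (ch$nseed > m$nseed) ch$d else m$d,
                            s = min(m$s, ch$s), e = max(m$e, ch$e),
                            nseed = m$nseed + ch$nseed)
        hit <- TRUE; break
      }
    }
    if (!hit) merged[[length(merged) + 1L]] <- as.list(ch[c("d", "s", "e", "nseed")])
  }

  sv <- seq_chars(seq)
  res <- list()
  for (m in merged) {
    d <- m$d
    s <- xdrop_extend(sv, m$s, d, -1L, p$xdrop, n)
    e <- xdrop_extend(sv, m$e, d, +1L, p$xdrop, n)
    L <- e - s + 1L
    partial <- FALSE
    if (L < p$min_ltr) {
      if (L >= 100L) partial <- TRUE else next
    }
    if (L > p$max_ltr) next
    span <- d + L
    if (span < p$min_element || span > p$max_element) next
    if (L > d) next                       # LTRs must not overlap
    ident <- alignment_identity(align_ltr(
      paste(sv[s:e], collapse = ""),
      paste(sv[(s + d):(e + d)], collapse = "")))
    if (ident < p$min_identity) next
    res[[length(res) + 1L]] <- data.frame(
      ltr5_start = s - 1L, ltr5_end = e, ltr3_start = s + d - 1L,
      ltr3_end = e + d, ltr_identity = ident, strand = "+",
      partial = partial, tsd_refined = FALSE)
  }
  if (!length(res)) return(empty_candidates()[, -1])
  res <- do.call(rbind, res)
  resolve_overlaps(res)
}

# Ungapped X-drop extension of the diagonal-d repeat from 1-based position
# `from` in direction `dir`; returns the new boundary (1-based, inclusive).
xdrop_extend <- function(sv, from, d, dir, xdrop, n) {
  best <- 0; sc <- 0; bi <- from
  i <- from + dir
  while (i >= 1L && i + d <= n) {
    sc <- sc + if (sv[i] == sv[i + d]) 1 else -2
    if (sc > best) { best <- sc; bi <- i }
    if (best - sc > xdrop) break
    i <- i + dir
  }
  bi
}

# Overlapping candidates collapse to the highest-identity, longest-LTR,
# leftmost representative.
resolve_overlaps <- function(cands) {
  L <- cands$ltr5_end - cands$ltr5_start
  o <- order(-cands$ltr_identity, -L, cands$ltr5_start)
  kept <- logical(nrow(cands))
  for (i in o) {
    s <- cands$ltr5_start[i]; e <- cands$ltr3_end[i]
    clash <- kept & cands$ltr3_end > s & cands$ltr5_start < e
    if (!any(clash)) kept[i] <- TRUE
  }
  out <- cands[kept, , drop = FALSE]
  out[order(out$ltr5_start), , drop = FALSE]
}

#' Detect the target-site duplication flanking a candidate
#'
#' Compares the `tsd_length` window immediately 5' of the element with the
#' window immediately 3' of it.
#'
#' @param seq contig sequence (character scalar).
#' @param cand one candidate row from [find_ltr_pairs()] (data.frame row or
#'   list with `ltr5_start` and `ltr3_end`).
#' @param tsd_length expected TSD length (default 5).
#' @param max_mismatch mismatch budget (default 0).
#' @return list of class `tsd_call`: `present`, and when present
#'   `tsd_sequence`, `left_start`, `right_start`, `length`, `mismatches`;
#'   `edge = TRUE` when the candidate sits at a contig edge.
#' @export
detect_tsd <- function(seq, cand, tsd_length = 5L, max_mismatch = 0L) {
  seq <- as_seq_set(seq)[[1]]
  s <- cand$ltr5_start; e <- cand$ltr3_end
  if (s < tsd_length || e + tsd_length > nchar(seq))
    return(structure(list(present = FALSE, edge = TRUE), class = "tsd_call"))
  left <- subseq_chr(seq, s - tsd_length, s)
  right <- subseq_chr(seq, e, e + tsd_length)
  mm <- hamming(left, right)
  if (mm > max_mismatch)
    return(structure(list(present = FALSE, edge = FALSE), class = "tsd_call"))
  structure(list(present = TRUE, tsd_sequence = left,
                 left_start = s - tsd_length, right_start = e,
                 length = tsd_length, mismatches = mm, edge = FALSE),
            class = "tsd_call")
}

#' Polish candidate boundaries against the TSD and LTR termini
#'
#' Shifts the element start and end (up to `slack` nt each) to jointly
#' maximize TSD agreement and the agreement of the two LTR termini; ties are
#' broken toward the unshifted position, making the operation idempotent.
#'
#' @param seq contig sequence.
#' @param cand candidate row (see [find_ltr_pairs()]).
#' @param tsd_length TSD length used for polishing.
#' @param slack maximum boundary shift in nt.
#' @param probe number of terminal nt compared between the LTR copies.
#' @return the candidate with updated coordinates, refreshed `ltr_identity`,
#'   and `tsd_refined` set when a perfect TSD was found.
#' @export
refine_boundaries <- function(seq, cand, tsd_length = 5L, slack = 25L,
                              probe = 12L) {
  seq <- as_seq_set(seq)[[1]]
  sv <- seq_chars(seq)
  n <- length(sv)
  s5 <- cand$ltr5_start; s3 <- cand$ltr3_start
  e5 <- cand$ltr5_end;  e3 <- cand$ltr3_end
  d <- s3 - s5
  win_match <- function(a, b, w, oob = -Inf) {
    ia <- (a + 1L):(a + w); ib <- (b + 1L):(b + w)
    if (min(ia, ib) < 1L || max(ia, ib) > n) return(oob)
    sum(sv[ia] == sv[ib])
  }
  shifts <- -slack:slack
  probe_out <- 8L
  # boundary contrast: the LTR copies must agree just inside the boundary
  # and disagree just outside it (host/TSD on one side, internal on the
  # other); agreement inside alone cannot place the boundary because the
  # copies match at any offset within the LTRs
  startm <- vapply(shifts, function(sh)
    win_match(s5 + sh, s3 + sh, probe) -
      win_match(s5 + sh - probe_out, s3 + sh - probe_out, probe_out, oob = 0), 0)
  endm <- vapply(shifts, function(sh)
    win_match(e5 + sh - probe, e3 + sh - probe, probe) -
      win_match(e5 + sh, e3 + sh, probe_out, oob = 0), 0)
  tsdm <- outer(shifts, shifts, Vectorize(function(a, b)
    win_match(s5 + a - tsd_length, e3 + b, tsd_length)))
  # canonical TG...CA LTR termini break ties between boundary placements
  # that are equally consistent with an exact duplication (a +/-1 shift of
  # both boundaries can reproduce the TSD exactly)
  safe_eq <- function(idx, ch) {
    ok <- idx >= 1L & idx <= n
    sum(sv[idx[ok]] == ch)
  }
  motif_s <- vapply(shifts, function(sh)
    safe_eq(c(s5, s3) + sh + 1L, "T") + safe_eq(c(s5, s3) + sh + 2L, "G"), 0)
  motif_e <- vapply(shifts, function(sh)
    safe_eq(c(e5, e3) + sh - 1L, "C") + safe_eq(c(e5, e3) + sh, "A"), 0)
  # exact TSDs anchor the boundary: reward a perfect duplication over
  # near-misses that happen to score well on terminal contrast alone
  total <- outer(startm, endm, `+`) + 2 * tsdm + 4 * (tsdm == tsd_length) +
    outer(motif_s, motif_e, `+`)
  # prefer the smallest shift at ties (idempotence)
  pen <- outer(abs(shifts), abs(shifts), `+`) * 1e-3
  total <- total - pen
  ix <- which(total == max(total), arr.ind = TRUE)[1L, ]
  a <- shifts[ix[1L]]; b <- shifts[ix[2L]]
  new_L <- (e5 - s5) + b - a
  if (new_L < probe) return(cand)         # refuse degenerate shrinkage
  cand$ltr5_start <- s5 + a
  cand$ltr3_start <- s3 + a
  cand$ltr5_end <- s5 + new_L + a
  cand$ltr3_end <- s3 + new_L + a
  cand$tsd_refined <- tsdm[ix[1L], ix[2L]] == tsd_length
  cand$ltr_identity <- alignment_identity(align_ltr(
    subseq_chr(seq, cand$ltr5_start, cand$ltr5_end),
    subseq_chr(seq, cand$ltr3_start, cand$ltr3_end)))
  cand
}
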