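# Genome-wide RT mining, pairwise-identity diversity statistics, and
# neighbor-joining dendrograms with bootstrap supports.  The NJ join
# criterion is the standard Saitou-Nei Q with deterministic tie-breaking;
# ape is used only as a tree container (phylo) and Newick parser.

#' Mine RT domains from genomic sequence
#'
#' Translates all six frames, splits at stop codons, and scores every offset
#' of each stop-free segment against the bundled RT profile.  Hits require a
#' bit score above `min_bits` and a segment longer than `min_aa`; overlapping
#' hits collapse to the best-scoring one.
#'
#' @param seqs named character vector of contigs (or DNAStringSet).
#' @param panel reference panel.
#' @param min_bits bit-score threshold (default 50).
#' @param min_aa minimum stop-free segment length in aa (default 200).
#' @return data.frame: `seq_id`, `strand`, `frame`, `nt_start`, `nt_end`
#'   (0-based half-open, forward-genome coordinates), `score`, `peptide`.
#' @export
mine_rt_domains <- function(seqs, panel = chromo_reference_panel(),
                            min_bits = 50, min_aa = 200L) {
  seqs <- as_seq_set(seqs)
  pssm <- panel$profiles$RT
  hits <- list()
  for (id in names(seqs)) {
    n <- nchar(seqs[[id]])
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seqs[[id]] else revcomp(seqs[[id]])
      for (frame in 0:2) {
        aa <- translate_nt(substr(s, frame + 1L, n))
        if (nchar(aa) <= min_aa) next
        va <- seq_chars(aa)
        bounds <- c(0L, which(va == "*"), length(va) + 1L)
        for (b in seq_len(length(bounds) - 1L)) {
          a0 <- bounds[b] + 1L; a1 <- bounds[b + 1L] - 1L
          if (a1 - a0 + 1L <= min_aa) next
          seg <- paste(va[a0:a1], collapse = "")
          sc <- scan_pssm_scores(pssm, seg)
          if (!length(sc) || max(sc) <= min_bits) next
          o <- which.max(sc)
          gaa <- a0 + o - 1L                       # aa pos in frame translation
          nt0 <- frame + 3L * (gaa - 1L)           # 0-based on scanned strand
          nt1 <- nt0 + 3L * pssm$width
          if (strand == "-") { tmp <- nt0; nt0 <- n - nt1; nt1 <- n - tmp }
          hits[[length(hits) + 1L]] <- data.frame(
            seq_id = id, strand = strand, frame = frame,
            nt_start = nt0, nt_end = nt1, score = max(sc),
            peptide = substr(seg, o, o + pssm$width - 1L))
        }
      }
    }
  }
  if (!length(hits))
    return(data.frame(seq_id = character(0), strand = character(0),
                      frame = integer(0), nt_start = integer(0),
                      nt_end = integer(0), score = numeric(0),
                      peptide = character(0)))
  h <- do.call(rbind, hits)
  # collapse overlapping hits (e.g. both strands over the same locus)
  h <- h[order(h$seq_id, -h$score), , drop = FALSE]
  kept <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    same <- kept & h$seq_id == h$seq_id[i] &
      h$nt_end > h$nt_start[i] & h$nt_start < h$nt_end[i]
    if (!any(same)) kept[i] <- TRUE
  }
  h <- h[kept, , drop = FALSE]
  h <- h[order(h$seq_id, h$nt_start), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Global-alignment identity between two peptides
#'
#' BLOSUM62, affine gaps (open 11, extend 1); identity is identical columns
#' over all aligned columns (gap columns included) by default.
#'
#' @param a,b peptides.
#' @param denominator "all" (gap columns included; default) or "ungapped".
#' @return fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b, denominator = c("all", "ungapped")) {
  denominator <- match.arg(denominator)
  if (!nchar(a) || !nchar(b)) stop_input("empty peptide")
  al <- align_protein(a, b)
  if (denominator == "all") alignment_identity(al)
  else alignment_identity_ungapped(al)
}

#' Pairwise identity matrix for a set of peptides
#'
#' @param peptides named character vector.
#' @inheritParams pairwise_identity
#' @return symmetric matrix with unit diagonal.
#' @export
identity_matrix <- function(peptides, denominator = "all") {
  n <- length(peptides)
  m <- diag(1, n)
  dimnames(m) <- list(names(peptides), names(peptides))
  if (n < 2L) return(m)
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    m[i, j] <- m[j, i] <- pairwise_identity(peptides[[i]], peptides[[j]],
                                            denominator)
  }
  m
}

#' Within-clade identity summary statistics
#'
#' Statistics over all unordered within-clade pairs; quartiles use the
#' inclusive linear-interpolation method (R quantile type 7).
#'
#' @param mat symmetric identity matrix with labels.
#' @param groups named vector mapping labels to clades.
#' @return data.frame: `clade`, `n` (members), `n_pairs`, `min`, `q1`,
#'   `median`, `mean`, `q3`, `max`; dispersion fields are NA for singleton
#'   clades.
#' @export
identity_stats <- function(mat, groups) {
  labs <- rownames(mat)
  groups <- groups[labs]
  out <- lapply(unique(groups), function(cl) {
    mem <- labs[groups == cl]
    if (length(mem) < 2L)
      return(data.frame(clade = cl, n = length(mem), n_pairs = 0L,
                        min = NA_real_, q1 = NA_real_, median = NA_real_,
                        mean = NA_real_, q3 = NA_real_, max = NA_real_))
    sub <- mat[mem, mem, drop = FALSE]
    vals <- sub[upper.tri(sub)]
    q <- quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(clade = cl, n = length(mem), n_pairs = length(vals),
               min = min(vals), q1 = q[1], median = q[2], mean = mean(vals),
               q3 = q[3], max = max(vals))
  })
  do.call(rbind, out)
}

# ---- neighbor joining --------------------------------------------------------

#' Saitou-Nei neighbor-joining tree
#'
#' Standard Q-criterion agglomeration with deterministic tie-breaking (the
#' pair whose smallest-contained-leaf labels sort first).  Negative branch
#' lengths are clamped to zero with the excess moved to the sister branch
#' (disable with `clamp_negative = FALSE`).
#'
#' @param d symmetric distance matrix with labels (or a `dist`).
#' @param clamp_negative clamp negative branch estimates (default TRUE).
#' @return an unrooted `ape::phylo` tree.
#' @export
build_nj_tree <- function(d, clamp_negative = TRUE) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-10))
    stop_input("distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 3L) stop_input("neighbor joining needs at least 3 taxa")
  labs <- rownames(d) %||% paste0("t", seq_len(n))
  D <- unname(d)
  sub <- labs                       # newick fragments per active node
  mins <- labs                      # smallest contained leaf label (tie-break)
  active <- seq_len(n)
  fmt <- function(x) sprintf("%.12g", x)

  while (length(active) > 3L) {
    r <- length(active)
    Dm <- D[active, active, drop = FALSE]
    R <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 & upper.tri(Q), arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      key <- apply(cand, 1L, function(ix) {
        ml <- sort(c(mins[active[ix[1]]], mins[active[ix[2]]]))
        paste(ml, collapse = "\r")
      })
      cand <- cand[order(key), , drop = FALSE]
    }
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    dij <- Dm[i, j]
    vi <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- dij - vi
    if (clamp_negative) {
      if (vi < 0) { vj <- vj + vi; vi <- 0 }
      if (vj < 0) { vi <- vi + vj; vj <- 0 }
      vi <- max(vi, 0); vj <- max(vj, 0)
    }
    ai <- active[i]; aj <- active[j]
    newd <- (D[ai, active] + D[aj, active] - dij) / 2
    u <- nrow(D) + 1L
    D <- rbind(cbind(D, 0), 0)
    D[u, active] <- newd; D[active, u] <- newd; D[u, u] <- 0
    sub <- c(sub, sprintf("(%s:%s,%s:%s)", sub[ai], fmt(vi), sub[aj], fmt(vj)))
    mins <- c(mins, min(mins[ai], mins[aj]))
    active <- c(setdiff(active, c(ai, aj)), u)
  }
  a <- active[1L]; b <- active[2L]; cc <- active[3L]
  va <- (D[a, b] + D[a, cc] - D[b, cc]) / 2
  vb <- (D[a, b] + D[b, cc] - D[a, cc]) / 2
  vc <- (D[a, cc] + D[b, cc] - D[a, b]) / 2
  if (clamp_negative) { va <- max(va, 0); vb <- max(vb, 0); vc <- max(vc, 0) }
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[a], fmt(va), sub[b], fmt(vb),
                 sub[cc], fmt(vc))
  ape::read.tree(text = nwk)
}

# Canonical keys of the non-trivial bipartitions of an unrooted phylo tree.
tree_bipartitions <- function(tr) {
  tips <- tr$tip.label
  pp <- ape::prop.part(tr)
  keys <- vapply(pp, function(ix) {
    s <- sort(tips[ix])
    if (length(s) == length(tips) || length(s) < 2L ||
        length(s) > length(tips) - 2L) return(NA_character_)
    if (min(tips) %in% s) s <- sort(setdiff(tips, s))
    paste(s, collapse = "\r")
  }, "")
  keys
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the full-alignment tree
#' the percentage of replicates containing its bipartition (stored as node
#' labels).
#'
#' @param msa named character vector of equal-length aligned sequences, or a
#'   character matrix (rows = sequences).
#' @param n_replicates number of bootstrap replicates (default 1000; 0 gives
#'   a tree without supports).
#' @param seed integer seed.
#' @param dist_fun function(matrix of residue characters) -> distance matrix;
#'   default is the p-distance over all columns (gap mismatches count).
#' @return `ape::phylo` with `node.label` holding supports (0-100).
#' @export
bootstrap_supports <- function(msa, n_replicates = 1000L, seed = 1L,
                               dist_fun = msa_p_distance) {
  m <- msa_char_matrix(msa)
  if (nrow(m) < 4L) stop_input("bootstrap needs an MSA with at least 4 rows")
  base <- build_nj_tree(dist_fun(m))
  if (n_replicates <= 0L) return(base)
  base_keys <- tree_bipartitions(base)
  counts <- setNames(numeric(length(base_keys)), base_keys)
  with_seed(seed, {
    for (rep in seq_len(n_replicates)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      tr <- build_nj_tree(dist_fun(m[, cols, drop = FALSE]))
      for (k in tree_bipartitions(tr))
        if (!is.na(k) && k %in% names(counts)) counts[k] <- counts[k] + 1
    }
  })
  supports <- round(100 * counts / n_replicates)
  base$node.label <- ifelse(is.na(base_keys), "",
                            as.character(supports[base_keys]))
  base$node.label[is.na(base$node.label)] <- ""
  base
}

msa_char_matrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  msa <- toupper(msa)
  w <- unique(nchar(msa))
  if (length(w) != 1L) stop_input("MSA rows must have equal length")
  m <- do.call(rbind, lapply(msa, seq_chars))
  rownames(m) <- names(msa)
  m
}

#' p-distance matrix from an MSA character matrix
#' @param m character matrix (rows = sequences).
#' @return symmetric distance matrix.
#' @export
msa_p_distance <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2L) return(d)
  for (i in 1:(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- mean(m[i, ] != m[j, ])
  d
}

#' Center-star multiple sequence alignment
#'
#' Aligns every sequence pairwise to the center and projects all gaps onto
#' shared columns (the classic center-star construction).
#'
#' @param peptides named character vector (>= 2).
#' @param center name or index of the center sequence (default: first).
#' @return named character vector of equal-length aligned rows (center
#'   included).
#' @export
center_star_msa <- function(peptides, center = 1L) {
  if (!length(peptides)) stop_input("center_star_msa: empty input")
  if (is.null(names(peptides))) names(peptides) <- paste0("s", seq_along(peptides))
  if (length(peptides) < 2L) return(peptides)
  if (is.character(center)) center <- match(center, names(peptides))
  cen <- peptides[[center]]
  others <- peptides[-center]
  C <- nchar(cen)
  parsed <- lapply(others, function(p) {
    ac <- aligned_chars(align_protein(cen, p))
    cpos <- cumsum(ac$p != "-")          # center chars consumed, per column
    list(ac = ac, cpos = cpos)
  })
  maxins <- integer(C + 1L)              # insertion slots before pos 1..C, and after C
  for (pr in parsed) {
    gaps <- pr$ac$p == "-"
    if (any(gaps)) {
      slot <- pr$cpos[gaps]              # insertion after this many center chars
      tab <- table(slot)
      ix <- as.integer(names(tab)) + 1L
      maxins[ix] <- pmax(maxins[ix], as.integer(tab))
    }
  }
  project <- function(pr) {
    # emit subject chars into the padded coordinate system
    out <- character(0)
    k <- 1L
    nc <- length(pr$ac$p)
    for (g in 0:C) {
      block <- character(0)
      while (k <= nc && pr$ac$p[k] == "-" && pr$cpos[k] == g) {
        block <- c(block, pr$ac$s[k]); k <- k + 1L
      }
      out <- c(out, block, rep("-", maxins[g + 1L] - length(block)))
      if (g < C) {
        if (k <= nc && pr$ac$p[k] != "-") { out <- c(out, pr$ac$s[k]); k <- k + 1L }
        else out <- c(out, "-")
      }
    }
    paste(out, collapse = "")
  }
  cen_row <- {
    cv <- seq_chars(cen)
    out <- character(0)
    for (g in 0:C) {
      out <- c(out, rep("-", maxins[g + 1L]))
      if (g < C) out <- c(out, cv[g + 1L])
    }
    paste(out, collapse = "")
  }
  rows <- c(setNames(cen_row, names(peptides)[center]),
            setNames(vapply(parsed, project, ""), names(others)))
  rows[names(peptides)]
}

#' Cluster elements into families by LTR identity
#'
#' Single-linkage clustering: element pairs whose LTR identity meets the
#' (inclusive) threshold join the same family.
#'
#' @param ltr_seqs named character vector of LTR sequences.
#' @param threshold identity threshold (default 0.80, inclusive).
#' @return named character vector of family labels ("F01", ...).
#' @export
cluster_families <- function(ltr_seqs, threshold = 0.80) {
  n <- length(ltr_seqs)
  if (!n) return(setNames(character(0), character(0)))
  if (is.null(names(ltr_seqs))) names(ltr_seqs) <- paste0("e", seq_len(n))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    if (ltr_identity(ltr_seqs[[i]], ltr_seqs[[j]]) >= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  fam <- match(roots, unique(roots))
  setNames(sprintf("F%02d", fam), names(ltr_seqs))
}

#' Screen transcripts for chromoviral hits
#'
#' Local alignment of each transcript against the element library; hits are
#' retained when identity exceeds `min_identity` over an aligned span longer
#' than `min_span` nt.  The best-scoring element per transcript is reported.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param element_library named character vector of element sequences.
#' @param min_identity identity floor (default 0.80, exclusive).
#' @param min_span aligned-span floor in nt (default 600, exclusive).
#' @return data.frame: `transcript_id`, `element_id`, `identity`, `span`,
#'   `score`, `retained`; one row per transcript with any local hit.
#' @export
est_screen <- function(transcripts, element_library,
                       min_identity = 0.80, min_span = 600L) {
  if (!length(element_library)) stop_config("empty element library")
  transcripts <- as_seq_set(transcripts)
  element_library <- as_seq_set(element_library)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  out <- list()
  for (tid in names(transcripts)) {
    best <- NULL
    for (eid in names(element_library)) {
      al <- Biostrings::pairwiseAlignment(transcripts[[tid]],
                                          element_library[[eid]],
                                          substitutionMatrix = mat,
                                          gapOpening = 5, gapExtension = 2,
                                          type = "local")
      sc <- Biostrings::score(al)
      if (is.null(best) || sc > best$score) {
        ac <- aligned_chars(al)
        span <- length(ac$p)
        ident <- sum(ac$p == ac$s & ac$p != "-") / span
        best <- list(element_id = eid, score = sc, span = span,
                     identity = ident)
      }
    }
    if (!is.null(best))
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = tid, element_id = best$element_id,
        identity = best$identity, span = best$span, score = best$score,
        retained = best$identity > min_identity && best$span > min_span)
  }
  if (!length(out))
    return(data.frame(transcript_id = character(0), element_id = character(0),
                      identity = numeric(0), span = integer(0),
                      score = numeric(0), retained = logical(0)))
  do.call(rbind, out)
}
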