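#' @importFrom stats runif quantile setNames rbinom
#' @importFrom utils write.table head tail
NULL

# ---- error conditions --------------------------------------------------------

stop_config <- function(msg, ...) {
  stop(structure(class = c("chromoscan_config_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_input <- function(msg, ...) {
  stop(structure(class = c("chromoscan_input_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# ---- seeded evaluation -------------------------------------------------------

# Evaluate `expr` under a private RNG stream; the caller's RNG state is
# untouched.  All stochastic operations in the package funnel through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# ---- nucleotide helpers ------------------------------------------------------

DNA <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#'
#' @param x character scalar (A/C/G/T/N, case-insensitive).
#' @return character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Random i.i.d. nucleotide sequence at a given GC fraction
#'
#' @param n length in nt.
#' @param gc GC fraction in \[0, 1\] (default 0.36, plant-like).
#' @return character scalar of length `n`.
#' @export
random_dna <- function(n, gc = 0.36) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA, n, replace = TRUE, prob = p), collapse = "")
}

subseq_chr <- function(x, start, end) {
  # 0-based half-open slice of a character scalar
  if (end <= start) return("")
  substr(x, start + 1L, end)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

hamming <- function(a, b) {
  va <- seq_chars(a); vb <- seq_chars(b)
  stopifnot(length(va) == length(vb))
  sum(va != vb)
}

# Translate a nucleotide string (trimmed to codon multiple); returns an
# amino-acid string with '*' for stops.
translate_nt <- function(nt) {
  n <- (nchar(nt) %/% 3L) * 3L
  if (n < 3L) return("")
  as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, n)),
    if.fuzzy.codon = "solve")))
}

# Reverse-translate a peptide with uniform codon choice (no stop codons).
reverse_translate <- function(pep) {
  if (!nchar(pep)) return("")
  codons <- .codon_table()
  v <- seq_chars(pep)
  unknown <- setdiff(v, names(codons))
  if (length(unknown)) stop_input("cannot reverse-translate residue(s): %s",
                                  paste(unique(unknown), collapse = ","))
  paste(vapply(v, function(a) {
    cs <- codons[[a]]
    cs[sample.int(length(cs), 1L)]
  }, ""), collapse = "")
}

.codon_env <- new.env(parent = emptyenv())
.codon_table <- function() {
  if (is.null(.codon_env$tab)) {
    gc <- Biostrings::GENETIC_CODE
    gc <- gc[gc != "*"]
    .codon_env$tab <- split(names(gc), gc)
  }
  .codon_env$tab
}

# ---- coercion of FASTA-ish inputs -------------------------------------------

# Accept a named character vector, a single string, or a DNAStringSet; return
# a named character vector (names auto-filled).
as_seq_set <- function(x) {
  if (methods::is(x, "XStringSet")) x <- setNames(as.character(x), names(x))
  if (!is.character(x)) stop_input("expected character sequences or a DNAStringSet")
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  toupper(x)
}

read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop_input("input file not found: %s", path)
  set <- tryCatch(
    if (type == "DNA") Biostrings::readDNAStringSet(path)
    else Biostrings::readAAStringSet(path),
    error = function(e) stop_input("malformed FASTA '%s': %s", path,
                                   conditionMessage(e)))
  # keep only the first whitespace-delimited token of each header
  nm <- sub("\\s.*$", "", names(set))
  setNames(as.character(set), nm)
}

write_fasta <- function(seqs, path, width = 70L) {
  seqs <- as_seq_set(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# ---- tiny string hash (provenance stamps) -----------------------------------

djb2_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
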