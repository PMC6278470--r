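# Low-level sequence helpers shared across modules. Sequences are plain
# uppercase character scalars over {A,C,G,T,N}; '-' appears only in gapped
# (alignment) strings.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x character scalar over `A,C,G,T,N` (case-insensitive).
#' @return character scalar, the reverse complement. `N` maps to `N`.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  rawToChar(rev(charToRaw(comp)))
}

# split a sequence string into a character vector of single letters
s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

c2s <- function(x) paste0(x, collapse = "")

# uppercase, RNA->DNA, map residual ambiguity letters to N; returns list
# (sequence, n_mapped) so callers can warn with a count
normalize_dna <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  ch <- s2c(x)
  bad <- !(ch %in% c(DNA_BASES, "N"))
  if (any(bad)) ch[bad] <- "N"
  list(sequence = c2s(ch), n_mapped = sum(bad))
}

# integer encoding for fast vectorized comparison; N positions get unique
# negative codes so N never matches anything (including another N)
seq_codes <- function(x, distinct_n = TRUE) {
  code <- utf8ToInt(x)
  if (distinct_n) {
    isn <- code == utf8ToInt("N")
    if (any(isn)) code[isn] <- -seq_len(sum(isn))
  }
  code
}

#' GC content of a DNA (sub)sequence
#'
#' Computes (G + C) / (A + C + G + T); `N` is excluded from both numerator
#' and denominator.
#'
#' @param sequence DNA string.
#' @param interval optional `c(start, end)` 1-based inclusive sub-interval.
#' @return fraction in `[0, 1]`.
#' @examples
#' gc_content("ATGC")
#' @export
gc_content <- function(sequence, interval = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  n <- nchar(sequence)
  if (!is.null(interval)) {
    if (length(interval) != 2L || interval[1] < 1L || interval[2] > n ||
        interval[1] > interval[2]) {
      stop("interval [", interval[1], ", ", interval[2],
           "] outside sequence of length ", n)
    }
    sequence <- substr(sequence, interval[1], interval[2])
  }
  ch <- s2c(toupper(sequence))
  gc <- sum(ch == "G" | ch == "C")
  at <- sum(ch == "A" | ch == "T")
  if (gc + at == 0L) stop("GC content undefined: no unambiguous bases")
  gc / (gc + at)
}

# 1-based inclusive interval overlap helpers
iv_contains <- function(outer, inner) {
  inner[1] >= outer[1] && inner[2] <= outer[2]
}
iv_overlaps <- function(a, b) a[1] <= b[2] && b[1] <= a[2]

#' Write rows to a tab-separated file
#'
#' Writes a data frame as UTF-8 TSV with a header row. Optional `meta` lines
#' are emitted first as `# `-prefixed comments so every output records its
#' provenance.
#'
#' @param rows a data frame (non-empty column set).
#' @param path output path.
#' @param meta optional character vector of metadata lines.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(rows, path, meta = NULL) {
  stopifnot(is.data.frame(rows))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(paste0("# ", meta), con)
  write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path input path; `# ` comment lines are skipped.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE, quote = "")
}

#' Write intervals as BED (0-based half-open)
#'
#' The only place where coordinates leave the package's 1-based inclusive
#' convention: conversion happens at this writer.
#'
#' @param intervals data frame with columns `chrom`, `start`, `end`, `name`
#'   (1-based inclusive).
#' @param path output path.
#' @param meta optional comment lines.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, meta = NULL) {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(intervals)))
  bed <- data.frame(chrom = intervals$chrom,
                    start = intervals$start - 1L,
                    end = intervals$end,
                    name = intervals$name)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(paste0("# ", meta), con)
  write.table(bed, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# standard metadata header lines for outputs
run_meta <- function(command = "", seed = NULL) {
  c(paste0("plastidmarker version ", as.character(packageVersion("plastidmarker"))),
    paste0("command: ", command),
    if (!is.null(seed)) paste0("seed: ", seed),
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
}
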