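# Pairwise and progressive multiple alignment, sliding-window identity
# profiling and variable-region ranking.
#
# Intended scale for the built-in progressive aligner is amplicon panels
# (<= ~50 sequences x ~5 kb). Whole-plastome comparisons should be run on an
# imported aligned FASTA (read_alignment) produced by a dedicated aligner.

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment. A gap run of length L costs
#' `gap_open + (L - 1) * gap_extend`. Traceback ties break deterministically,
#' preferring diagonal, then up (gap in `b`), then left (gap in `a`).
#'
#' @param a,b non-empty DNA strings.
#' @param match,mismatch,gap_open,gap_extend scoring parameters; penalties
#'   are negative. Defaults (1, -1, -2, -1) are neutral for closely related
#'   sequences.
#' @return list of class `PairwiseAlignment`: `gapped_a`, `gapped_b`,
#'   `score`, `identity` (matches over aligned columns).
#' @export
global_align <- function(a, b, match = 1, mismatch = -1,
                         gap_open = -2, gap_extend = -1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty input sequence")
  res <- gotoh_align_cpp(toupper(a), toupper(b), match, mismatch,
                         gap_open, gap_extend)
  ca <- s2c(res$a); cb <- s2c(res$b)
  matches <- sum(ca == cb & ca %in% DNA_BASES)
  structure(list(gapped_a = res$a, gapped_b = res$b, score = res$score,
                 identity = matches / length(ca)),
            class = "PairwiseAlignment")
}

#' Construct a multiple alignment
#'
#' @param seqs named character vector (or list) of equal-length gapped
#'   sequences over `A,C,G,T,N,-`.
#' @param labels optional named character vector mapping sample id to
#'   species; required downstream by the diagnostic caller.
#' @param drop_allgap drop all-gap columns (with a message) instead of
#'   erroring.
#' @return object of class `MultipleAlignment` with fields `seqs` (named
#'   character vector), `labels`, `length`.
#' @export
multiple_alignment <- function(seqs, labels = NULL, drop_allgap = FALSE) {
  seqs <- vapply(seqs, toupper, character(1))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all alignment rows must be named")
  }
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("gapped sequences have unequal lengths")
  mat <- aln_matrix_raw(seqs)
  allgap <- colSums(mat != "-") == 0L
  if (any(allgap)) {
    if (!drop_allgap) stop(sum(allgap), " all-gap column(s) in alignment")
    message("removed ", sum(allgap), " all-gap column(s)")
    mat <- mat[, !allgap, drop = FALSE]
    seqs <- setNames(apply(mat, 1L, paste0, collapse = ""), names(seqs))
    L <- ncol(mat)
  }
  if (!is.null(labels)) {
    missing <- setdiff(names(seqs), names(labels))
    if (length(missing)) stop("unlabeled sample(s): ",
                              paste(missing, collapse = ", "))
    labels <- labels[names(seqs)]
  }
  structure(list(seqs = seqs, labels = labels, length = unname(L)),
            class = "MultipleAlignment")
}

#' @export
print.MultipleAlignment <- function(x, ...) {
  cat("MultipleAlignment:", length(x$seqs), "sequences x", x$length,
      "columns\n")
  invisible(x)
}

# character matrix (rows = samples) from gapped sequences
aln_matrix_raw <- function(seqs) {
  do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}

#' Alignment as a character matrix
#' @param msa a `MultipleAlignment`.
#' @return character matrix, rows = samples (named), columns = positions.
#' @export
aln_matrix <- function(msa) {
  m <- aln_matrix_raw(msa$seqs)
  rownames(m) <- names(msa$seqs)
  m
}

#' Remove gaps from an alignment row
#' @param x gapped sequence string.
#' @return ungapped sequence.
#' @export
degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Write a multiple alignment as aligned FASTA
#' @param msa a `MultipleAlignment`.
#' @param path output path.
#' @export
write_alignment <- function(msa, path) {
  write_fasta(as.list(msa$seqs), path)
}

# k-mer frequency distance used for the guide tree
kmer_distance_matrix <- function(seqs, k = 3L) {
  kmers <- expand.grid(rep(list(DNA_BASES), k), stringsAsFactors = FALSE)
  kmers <- apply(kmers, 1L, paste0, collapse = "")
  freq <- vapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(setNames(numeric(length(kmers)), kmers))
    starts <- seq_len(n - k + 1L)
    tab <- table(factor(substring(s, starts, starts + k - 1L),
                        levels = kmers))
    as.numeric(tab) / length(starts)
  }, numeric(length(kmers)))
  d <- as.matrix(stats::dist(t(freq)))
  dimnames(d) <- list(names(seqs), names(seqs))
  d
}

# frequency profile (6 x L: A,C,G,T,N,gap) of a set of gapped rows
profile_freq <- function(seqs) {
  m <- aln_matrix_raw(seqs)
  L <- ncol(m)
  lv <- c(DNA_BASES, "N", "-")
  out <- matrix(0, nrow = 6L, ncol = L)
  for (r in seq_len(6L)) out[r, ] <- colMeans(m == lv[r])
  out
}

# splice gap columns into gapped sequences following a merge path
apply_path <- function(seqs, path, consume_op) {
  mats <- strsplit(seqs, "", fixed = TRUE)
  take <- path == consume_op | path == 0L
  out_len <- length(path)
  vapply(mats, function(ch) {
    res <- rep("-", out_len)
    res[take] <- ch
    paste0(res, collapse = "")
  }, character(1))
}

#' Progressive multiple sequence alignment
#'
#' Builds a guide order by neighbor-joining on k-mer frequency distances and
#' merges sub-alignments by affine-gap profile-profile alignment.
#'
#' @param seqs named character vector/list of >= 2 ungapped DNA sequences.
#' @param labels optional id -> species map stored on the result.
#' @param match,mismatch,gap_open,gap_extend scoring parameters (see
#'   [global_align()]).
#' @param k guide-tree k-mer length.
#' @return a `MultipleAlignment`.
#' @export
progressive_msa <- function(seqs, labels = NULL, match = 1, mismatch = -1,
                            gap_open = -2, gap_extend = -1, k = 3L) {
  seqs <- vapply(seqs, toupper, character(1))
  if (length(seqs) < 2L) stop("progressive_msa needs >= 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (length(seqs) == 2L) {
    pa <- global_align(seqs[[1]], seqs[[2]], match, mismatch,
                       gap_open, gap_extend)
    return(multiple_alignment(setNames(c(pa$gapped_a, pa$gapped_b),
                                       names(seqs)), labels = labels))
  }
  d <- kmer_distance_matrix(seqs, k = k)
  joins <- nj_join_order(d)
  # groups of gapped member sequences, keyed by current node id
  groups <- lapply(seq_along(seqs), function(i) seqs[i])
  merge2 <- function(ga, gb) {
    path <- profile_align_cpp(profile_freq(ga), profile_freq(gb),
                              match, mismatch, gap_open, gap_extend)
    c(apply_path(ga, path, 1L), apply_path(gb, path, 2L))
  }
  for (jn in joins) {
    groups[[length(groups) + 1L]] <- merge2(groups[[jn[1]]], groups[[jn[2]]])
    groups[jn] <- list(NULL, NULL)
  }
  remaining <- which(!vapply(groups, is.null, logical(1)))
  acc <- groups[[remaining[1]]]
  for (i in remaining[-1]) acc <- merge2(acc, groups[[i]])
  multiple_alignment(acc[names(seqs)], labels = labels)
}

#' Sliding-window identity profile
#'
#' A column is identical when it contains no gap, no `N`, and all samples
#' carry the same base. Windows are tiled from column 1 by `step`; a final
#' window clipped by the alignment end is included and flagged `partial`.
#'
#' @param msa a `MultipleAlignment`.
#' @param window window width in columns (default 200, resolving
#'   few-hundred-bp spacers).
#' @param step step in columns (default 50).
#' @return data frame with `window_start`, `window_end`, `identity_pct`,
#'   `partial`.
#' @export
identity_profile <- function(msa, window = 200L, step = 50L) {
  if (window > msa$length) stop("window (", window, ") > alignment length (",
                                msa$length, ")")
  stopifnot(step >= 1L)
  m <- aln_matrix(msa)
  base <- m[1L, ]
  same <- colSums(m != matrix(base, nrow(m), ncol(m), byrow = TRUE)) == 0L
  ident <- same & (base %in% DNA_BASES)
  starts <- seq(1L, msa$length, by = step)
  ends <- pmin(starts + window - 1L, msa$length)
  keep <- starts <= msa$length
  starts <- starts[keep]; ends <- ends[keep]
  pct <- vapply(seq_along(starts), function(i) {
    100 * mean(ident[starts[i]:ends[i]])
  }, numeric(1))
  data.frame(window_start = starts, window_end = ends,
             identity_pct = pct,
             partial = (starts + window - 1L) > msa$length)
}

#' Rank variable regions from an identity profile
#'
#' Merges maximal runs of windows whose identity falls below `threshold`
#' into candidate intervals, sorted by ascending mean identity (most
#' divergent first).
#'
#' @param profile data frame from [identity_profile()].
#' @param threshold identity percentage below which a window is variable
#'   (default 90).
#' @param features optional list of `GeneFeature` for context labels.
#' @return data frame with `start`, `end`, `mean_identity`, `n_windows` and
#'   (when `features` given) `context`.
#' @export
rank_variable_regions <- function(profile, threshold = 90, features = NULL) {
  low <- profile$identity_pct < threshold
  empty <- data.frame(start = integer(), end = integer(),
                      mean_identity = numeric(), n_windows = integer())
  if (!any(low)) return(empty)
  r <- rle(low)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- lapply(which(r$values), function(j) {
    idx <- starts[j]:ends[j]
    data.frame(start = min(profile$window_start[idx]),
               end = max(profile$window_end[idx]),
               mean_identity = mean(profile$identity_pct[idx]),
               n_windows = length(idx))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$mean_identity), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(features)) {
    out$context <- vapply(seq_len(nrow(out)), function(i) {
      iv <- c(out$start[i], out$end[i])
      hit <- unlist(lapply(features, function(f) {
        if (any(apply(f$intervals, 1L, iv_overlaps, b = iv))) f$name
        else character(0)
      }))
      if (length(hit)) paste(unique(hit), collapse = ",") else "intergenic"
    }, character(1))
  }
  out
}
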