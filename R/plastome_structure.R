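# Quadripartite plastome structure: inverted-repeat detection, LSC/IRb/SSC/IRa
# partitioning, per-region length and GC statistics.
#
# Plastomes carry two inverted-repeat copies (IRa/IRb, typically 10-30 kb and
# identical) separating a large and a small single-copy region. We detect the
# IR pair directly from sequence by anchoring exact seed k-mers against the
# reverse complement and extending bidirectionally, then label the two
# single-copy gaps by length (the longer one is the LSC).

#' Find the longest inverted-repeat pair in a sequence
#'
#' Anchors exact seed k-mers of the sequence against its reverse complement,
#' groups anchors by diagonal, and extends each anchor bidirectionally,
#' optionally tolerating mismatches up to `max_mismatch_frac` of the extended
#' length. Among qualifying pairs the longest is returned; equal lengths break
#' toward the smaller start of the left copy.
#'
#' @param sequence DNA string (length at least `2 * min_ir_len`).
#' @param min_ir_len minimum acceptable repeat length in bp (default 1000:
#'   real plastome IRs are 10-30 kb, the floor only suppresses short
#'   palindromes).
#' @param max_mismatch_frac allowed mismatch fraction in `[0, 0.05)`;
#'   default 0 (plastome IR copies are typically identical).
#' @param k seed k-mer length (default 21).
#' @return `NULL` if no pair reaches `min_ir_len`, else a list with
#'   `a = c(start, end)`, `b = c(start, end)` (1-based inclusive, `a` before
#'   `b`), `length`, and `mismatches`.
#' @export
find_longest_inverted_repeat <- function(sequence, min_ir_len = 1000L,
                                         max_mismatch_frac = 0,
                                         k = 21L) {
  n <- nchar(sequence)
  if (n < 2L * min_ir_len) {
    stop("sequence length ", n, " < 2 * min_ir_len (", 2L * min_ir_len, ")")
  }
  stopifnot(max_mismatch_frac >= 0, max_mismatch_frac < 0.05)
  rc <- revcomp(sequence)
  sc <- seq_codes(sequence)
  rcc <- seq_codes(rc)

  k <- min(k, min_ir_len)
  starts <- seq_len(n - k + 1L)
  kms <- substring(sequence, starts, starts + k - 1L)
  kmr <- substring(rc, starts, starts + k - 1L)
  # positions in rc of every k-mer value, then all (i, p) anchor pairs
  by_kmer <- split(starts, kmr)
  hit <- kms %in% names(by_kmer)
  if (!any(hit)) return(NULL)
  ii <- starts[hit]
  plist <- by_kmer[kms[hit]]
  i_all <- rep.int(ii, lengths(plist))
  p_all <- unlist(plist, use.names = FALSE)
  # one representative anchor (minimum i) per diagonal d = i - p
  d <- i_all - p_all
  ord <- order(d, i_all)
  first <- !duplicated(d[ord])
  last <- !duplicated(d[ord], fromLast = TRUE)
  pick <- first | last       # two disjoint runs may share a diagonal
  anchors <- unique(cbind(i = i_all[ord][pick], p = p_all[ord][pick]))

  best <- NULL
  for (r in seq_len(nrow(anchors))) {
    i0 <- anchors[r, "i"]; p0 <- anchors[r, "p"]
    # greedy bidirectional extension with a running mismatch budget
    left <- 0L; right <- k - 1L; mm <- 0L
    repeat {
      len <- right - left + 1L
      iR <- i0 + right + 1L; pR <- p0 + right + 1L
      iL <- i0 + left - 1L; pL <- p0 + left - 1L
      extended <- FALSE
      if (iR <= n && pR <= n) {
        ok <- sc[iR] == rcc[pR]
        if (ok || (mm + 1L) / (len + 1L) <= max_mismatch_frac) {
          right <- right + 1L
          if (!ok) mm <- mm + 1L
          extended <- TRUE
        }
      }
      if (!extended && iL >= 1L && pL >= 1L) {
        ok <- sc[iL] == rcc[pL]
        if (ok || (mm + 1L) / (len + 1L) <= max_mismatch_frac) {
          left <- left - 1L
          if (!ok) mm <- mm + 1L
          extended <- TRUE
        }
      }
      if (!extended) break
    }
    a1 <- i0 + left; L <- right - left + 1L
    p1 <- p0 + left
    # rc position p matches genome position n - p + 1; the right copy is
    # [n - (p1 + L - 1) + 1, n - p1 + 1]
    b2 <- n - p1 + 1L
    b1 <- b2 - L + 1L
    # require disjoint copies with the left one first; trim symmetric
    # overlap (a palindrome spanning the midpoint)
    if (b1 <= a1 + L - 1L) {
      Lmax <- (b2 - a1 + 1L) %/% 2L
      trim <- L - Lmax
      if (trim > 0L) { L <- Lmax; b1 <- b1 + trim }
      # trimming from the a-right/b-left end keeps a1 fixed
      if (L < 1L) next
      mm <- sum(sc[a1:(a1 + L - 1L)] != rcc[p1:(p1 + L - 1L)])
    }
    if (a1 + L - 1L >= b1) next
    if (L < min_ir_len) next
    if (is.null(best) || L > best$length ||
        (L == best$length && a1 < best$a[1L])) {
      best <- list(a = unname(c(a1, a1 + L - 1L)), b = unname(c(b1, b2)),
                   length = unname(L), mismatches = unname(mm))
    }
  }
  best
}

#' Partition a genome into LSC/IRb/SSC/IRa
#'
#' Labels the two single-copy gaps between the IR copies (on the circle) as
#' LSC (the longer) and SSC (the shorter), and reports the partition on the
#' canonical rotation that puts LSC position 1 first. The IR copy following
#' the LSC is IRb; the copy following the SSC is IRa. Input-linearization
#' coordinates are preserved in the `input_coords` provenance field.
#'
#' @param genome a `GenomeRecord`.
#' @param ir result of [find_longest_inverted_repeat()] on `genome$sequence`.
#' @return object of class `QuadripartitePartition` with fields `lsc`, `irb`,
#'   `ssc`, `ira` (canonical coordinates), `ir_length`, `mismatches`,
#'   `offset` (0-based left-rotation applied), `input_coords`.
#' @export
partition_quadripartite <- function(genome, ir) {
  stopifnot(inherits(genome, "GenomeRecord"), is.list(ir))
  n <- genome$length
  a <- ir$a; b <- ir$b
  if (a[2] >= b[1]) stop("degenerate structure: IR copies overlap")
  # gap between the copies, and the wrapping gap around the origin
  gap_mid_len <- b[1] - a[2] - 1L
  gap_out_len <- (n - b[2]) + (a[1] - 1L)
  if (gap_mid_len == 0L || gap_out_len == 0L) {
    stop("degenerate structure: zero-length single-copy gap")
  }
  lsc_is_outer <- gap_out_len > gap_mid_len ||
    (gap_out_len == gap_mid_len && TRUE)  # tie: LSC is the gap before copy A
  if (lsc_is_outer) {
    lsc_len <- gap_out_len; ssc_len <- gap_mid_len
    # canonical order LSC, IRb(=copy A), SSC, IRa(=copy B);
    # LSC starts at b[2]+1 on the circle
    offset <- b[2] %% n
  } else {
    lsc_len <- gap_mid_len; ssc_len <- gap_out_len
    # LSC is between the copies; IRb is copy B, IRa is copy A
    offset <- a[2] %% n
  }
  irl <- ir$length
  lsc <- c(1L, lsc_len)
  irb <- c(lsc_len + 1L, lsc_len + irl)
  ssc <- c(lsc_len + irl + 1L, lsc_len + irl + ssc_len)
  ira <- c(lsc_len + irl + ssc_len + 1L, n)
  stopifnot(ira[2] - ira[1] + 1L == irl)
  structure(list(lsc = lsc, irb = irb, ssc = ssc, ira = ira,
                 ir_length = irl, mismatches = ir$mismatches,
                 offset = offset,
                 input_coords = list(a = a, b = b)),
            class = "QuadripartitePartition")
}

#' @export
print.QuadripartitePartition <- function(x, ...) {
  cat("Quadripartite partition (canonical rotation, offset ", x$offset, "):\n",
      sep = "")
  for (r in c("lsc", "irb", "ssc", "ira")) {
    iv <- x[[r]]
    cat(sprintf("  %-4s %8d..%-8d (%d bp)\n", toupper(r), iv[1], iv[2],
                iv[2] - iv[1] + 1L))
  }
  invisible(x)
}

#' Rotate a genome to its canonical (LSC-first) linearization
#'
#' Applies the left-rotation recorded in a partition's `offset`. Features are
#' shifted accordingly; a feature that ends up crossing the new origin is
#' split into two intervals and flagged `wraps`.
#'
#' @param genome a `GenomeRecord`.
#' @param partition a `QuadripartitePartition` from the same genome.
#' @return rotated `GenomeRecord`.
#' @export
rotate_genome <- function(genome, partition) {
  off <- partition$offset
  n <- genome$length
  if (off == 0L) return(genome)
  seq2 <- paste0(substr(genome$sequence, off + 1L, n),
                 substr(genome$sequence, 1L, off))
  shift <- function(pos) ((pos - off - 1L) %% n) + 1L
  feats <- lapply(genome$features, function(f) {
    ivs <- f$intervals
    out <- NULL
    wraps <- f$wraps
    for (r in seq_len(nrow(ivs))) {
      s <- shift(ivs[r, 1L]); e <- shift(ivs[r, 2L])
      if (s <= e) out <- rbind(out, c(s, e))
      else { out <- rbind(out, c(s, n), c(1L, e)); wraps <- TRUE }
    }
    gene_feature(f$name, f$kind, out, f$strand, wraps)
  })
  genome_record(genome$id, seq2, feats, source = genome$source)
}

#' Per-region length and GC table
#'
#' @param genome a `GenomeRecord` on the canonical rotation.
#' @param partition a `QuadripartitePartition`.
#' @return data frame with rows LSC, IRb, SSC, IRa and `genome`, columns
#'   `region`, `length`, `gc` (fraction) and `gc_pct` (1-decimal percent).
#'   In prose summaries the IR GC is quoted once, as the IRb value (the two
#'   copies are reverse complements, so their GC is identical).
#' @export
region_gc <- function(genome, partition) {
  regions <- list(LSC = partition$lsc, IRb = partition$irb,
                  SSC = partition$ssc, IRa = partition$ira)
  rows <- lapply(names(regions), function(r) {
    iv <- regions[[r]]
    g <- gc_content(genome$sequence, iv)
    data.frame(region = r, length = iv[2] - iv[1] + 1L,
               gc = g, gc_pct = round(100 * g, 1))
  })
  g <- gc_content(genome$sequence)
  rows <- c(rows, list(data.frame(region = "genome", length = genome$length,
                                  gc = g, gc_pct = round(100 * g, 1))))
  do.call(rbind, rows)
}

#' One-call quadripartite analysis
#'
#' Convenience wrapper: detect the IR, partition, rotate to canonical form,
#' and tabulate region statistics.
#'
#' @param genome a `GenomeRecord`.
#' @param min_ir_len,max_mismatch_frac passed to
#'   [find_longest_inverted_repeat()].
#' @return list with `partition`, `genome` (rotated), `table` (region_gc).
#' @export
analyze_structure <- function(genome, min_ir_len = 1000L,
                              max_mismatch_frac = 0) {
  ir <- find_longest_inverted_repeat(genome$sequence, min_ir_len,
                                     max_mismatch_frac)
  if (is.null(ir)) stop("no inverted repeat of length >= ", min_ir_len,
                        " found in ", genome$id)
  part <- partition_quadripartite(genome, ir)
  rot <- rotate_genome(genome, part)
  list(partition = part, genome = rot, table = region_gc(rot, part))
}
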