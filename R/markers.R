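# Species-diagnostic event calling from labeled alignments, and
# conserved-flank primer-pair design around variable targets.
#
# A column is diagnostic for species S when (i) every S sample carries the
# same state, (ii) that state is absent from every non-S sample, and (iii)
# for substitutions, all states involved are unambiguous bases (no gap, no
# N). Indel events are maximal runs of columns gapped in exactly one
# species' samples (deletion) or gapped in everyone else (insertion).

empty_events <- function() {
  data.frame(event_type = character(), species = character(),
             aln_start = integer(), aln_end = integer(),
             target_allele = character(), other_alleles = character(),
             stringsAsFactors = FALSE)
}

# maximal runs of TRUE in a logical vector -> matrix (start, end)
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Call species-diagnostic substitutions and indels
#'
#' @param msa a labeled `MultipleAlignment` with >= 2 species.
#' @param min_samples_per_species minimum samples required per species
#'   (default 2).
#' @return data frame of events with columns `event_type` (`substitution`,
#'   `deletion`, `insertion`, plus merged `haplotype_block` convenience rows
#'   for runs of consecutive substitutions diagnosing the same species),
#'   `species`, `aln_start`, `aln_end`, `target_allele`, `other_alleles`
#'   (per-species representative states, `"sp=X"` joined by `|`), sorted by
#'   `aln_start`.
#' @export
call_diagnostic_events <- function(msa, min_samples_per_species = 2L) {
  stopifnot(inherits(msa, "MultipleAlignment"))
  if (is.null(msa$labels)) stop("unlabeled samples: species labels required")
  m <- aln_matrix(msa)
  species <- unique(unname(msa$labels))
  if (length(species) < 2L) stop("need >= 2 species")
  counts <- table(msa$labels)
  short <- names(counts)[counts < min_samples_per_species]
  if (length(short)) {
    stop("species with < ", min_samples_per_species, " samples: ",
         paste(short, collapse = ", "))
  }
  L <- ncol(m)
  in_acgt <- matrix(m %in% DNA_BASES, nrow = nrow(m))
  is_gap <- m == "-"

  per_sp <- lapply(species, function(sp) {
    rows <- which(msa$labels[rownames(m)] == sp)
    ms <- m[rows, , drop = FALSE]
    fixed <- colSums(ms != matrix(ms[1L, ], nrow(ms), L, byrow = TRUE)) == 0L
    list(rows = rows, allele = ms[1L, ], fixed = fixed,
         all_gap = colSums(!is_gap[rows, , drop = FALSE]) == 0L,
         none_gap = colSums(is_gap[rows, , drop = FALSE]) == 0L)
  })
  names(per_sp) <- species

  events <- list()
  other_states <- function(sp, cols) {
    vapply(setdiff(species, sp), function(o) {
      paste0(o, "=", paste0(per_sp[[o]]$allele[cols], collapse = ""))
    }, character(1)) |> paste(collapse = "|")
  }

  for (sp in species) {
    ps <- per_sp[[sp]]
    others <- setdiff(seq_len(nrow(m)), ps$rows)
    mo <- m[others, , drop = FALSE]
    others_acgt <- colSums(!in_acgt[others, , drop = FALSE]) == 0L
    others_nogap <- colSums(is_gap[others, , drop = FALSE]) == 0L
    others_allgap <- colSums(!is_gap[others, , drop = FALSE]) == 0L
    x_in_others <- colSums(mo == matrix(ps$allele, nrow(mo), L,
                                        byrow = TRUE)) > 0L
    # substitutions: column-local
    sub <- ps$fixed & (ps$allele %in% DNA_BASES) & others_acgt & !x_in_others
    for (c0 in which(sub)) {
      events[[length(events) + 1L]] <- data.frame(
        event_type = "substitution", species = sp,
        aln_start = c0, aln_end = c0, target_allele = ps$allele[c0],
        other_alleles = other_states(sp, c0))
    }
    # haplotype-block convenience rows for consecutive diagnostic columns
    if (sum(sub) >= 2L) {
      for (r in seq_len(nrow(true_runs(sub)))) {
        run <- true_runs(sub)[r, ]
        if (run["end"] > run["start"]) {
          cols <- run["start"]:run["end"]
          events[[length(events) + 1L]] <- data.frame(
            event_type = "haplotype_block", species = sp,
            aln_start = run[["start"]], aln_end = run[["end"]],
            target_allele = paste0(ps$allele[cols], collapse = ""),
            other_alleles = other_states(sp, cols))
        }
      }
    }
    # deletion in sp: sp all gap, all others non-gap
    del <- ps$all_gap & others_nogap
    if (any(del)) {
      runs <- true_runs(del)
      for (r in seq_len(nrow(runs))) {
        cols <- runs[r, "start"]:runs[r, "end"]
        events[[length(events) + 1L]] <- data.frame(
          event_type = "deletion", species = sp,
          aln_start = runs[[r, "start"]], aln_end = runs[[r, "end"]],
          target_allele = strrep("-", length(cols)),
          other_alleles = other_states(sp, cols))
      }
    }
    # insertion in sp: sp non-gap (and fixed), all others gapped
    ins <- ps$none_gap & ps$fixed & others_allgap
    if (any(ins)) {
      runs <- true_runs(ins)
      for (r in seq_len(nrow(runs))) {
        cols <- runs[r, "start"]:runs[r, "end"]
        events[[length(events) + 1L]] <- data.frame(
          event_type = "insertion", species = sp,
          aln_start = runs[[r, "start"]], aln_end = runs[[r, "end"]],
          target_allele = paste0(ps$allele[cols], collapse = ""),
          other_alleles = other_states(sp, cols))
      }
    }
  }
  if (length(events) == 0L) return(empty_events())
  out <- do.call(rbind, events)
  out <- out[order(out$aln_start, out$aln_end, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map alignment columns of an event to reference coordinates
#'
#' Converts `aln_start..aln_end` to 1-based positions on the de-gapped
#' reference sample. When the reference is gapped across the whole event
#' (the event is a deletion shared by the reference), the event maps to the
#' flanking pair `(left_pos, left_pos + 1)` with `between = TRUE`.
#'
#' @param event one event row (list or single-row data frame with
#'   `aln_start`, `aln_end`).
#' @param msa the `MultipleAlignment` the event was called on.
#' @param reference sample id to map onto.
#' @return list with `ref_start`, `ref_end`, `between`.
#' @export
map_event_to_reference <- function(event, msa, reference) {
  if (!reference %in% names(msa$seqs)) {
    stop("reference sample not in alignment: ", reference)
  }
  ch <- s2c(msa$seqs[[reference]])
  cum <- cumsum(ch != "-")
  s <- event$aln_start; e <- event$aln_end
  stopifnot(s >= 1L, e <= length(ch), s <= e)
  ref_start <- cum[s] + (ch[s] == "-")
  ref_end <- cum[e]
  if (ref_start > ref_end) {        # reference gapped across the event
    left <- cum[s]
    return(list(ref_start = left, ref_end = left + 1L, between = TRUE))
  }
  list(ref_start = unname(ref_start), ref_end = unname(ref_end),
       between = FALSE)
}

# conserved column mask: no gap, no N, all samples identical
conserved_columns <- function(msa) {
  m <- aln_matrix(msa)
  base <- m[1L, ]
  same <- colSums(m != matrix(base, nrow(m), ncol(m), byrow = TRUE)) == 0L
  same & (base %in% DNA_BASES)
}

#' Find fully conserved flanking windows around a target interval
#'
#' A window qualifies when all `flank_len` columns are gap-free and
#' identical across every sample. Candidates are returned nearest-first.
#'
#' @param msa a `MultipleAlignment`.
#' @param target `c(start, end)` alignment-column interval.
#' @param flank_len window width in columns (default 20).
#' @return list with data frames `left` and `right` (`start`, `end`,
#'   `distance` to the target); either may have zero rows.
#' @export
find_conserved_flanks <- function(msa, target, flank_len = 20L) {
  stopifnot(target[1] >= 1L, target[2] <= msa$length, target[1] <= target[2])
  cons <- conserved_columns(msa)
  L <- msa$length
  ok_start <- which(vapply(seq_len(L - flank_len + 1L), function(s) {
    all(cons[s:(s + flank_len - 1L)])
  }, logical(1)))
  ends <- ok_start + flank_len - 1L
  left <- ok_start[ends < target[1]]
  right <- ok_start[ok_start > target[2]]
  ldf <- data.frame(start = left, end = left + flank_len - 1L,
                    distance = target[1] - (left + flank_len - 1L))
  ldf <- ldf[order(ldf$distance), , drop = FALSE]
  rdf <- data.frame(start = right, end = right + flank_len - 1L,
                    distance = right - target[2])
  rdf <- rdf[order(rdf$distance), , drop = FALSE]
  rownames(ldf) <- rownames(rdf) <- NULL
  list(left = ldf, right = rdf)
}

#' Primer melting temperature (Wallace rule)
#'
#' `Tm = 2 * (A + T) + 4 * (G + C)` degrees C; deterministic and adequate
#' for the short (18-24 nt) primers designed here.
#'
#' @param primer DNA string, length >= 8, strictly `A,C,G,T`.
#' @param method only `"wallace"`.
#' @return temperature in degrees C.
#' @export
primer_tm <- function(primer, method = "wallace") {
  method <- match.arg(method, "wallace")
  ch <- s2c(toupper(primer))
  if (length(ch) < 8L) stop("primer shorter than 8 nt")
  if (!all(ch %in% DNA_BASES)) stop("non-ACGT character in primer")
  2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C"))
}

# longest run of contiguous Watson-Crick complementarity between the
# 3'-terminal `tail` of `a` and any stretch of `b` (antiparallel)
comp_run_3prime <- function(a, b, tail = 8L) {
  x <- substr(a, max(1L, nchar(a) - tail + 1L), nchar(a))
  y <- revcomp(b)      # complementary run == common substring with revcomp
  xs <- s2c(x); ys <- s2c(y)
  best <- 0L
  prev <- integer(length(ys))
  for (i in seq_along(xs)) {
    cur <- integer(length(ys))
    hit <- which(ys == xs[i])
    for (j in hit) {
      cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
      if (cur[j] > best) best <- cur[j]
    }
    prev <- cur
  }
  best
}

max_homopolymer <- function(x) {
  r <- rle(s2c(x))
  max(r$lengths)
}

primer_gc_pct <- function(x) 100 * gc_content(x)

#' Design conserved-flank primer pairs around a target
#'
#' Enumerates all 100%-conserved, gap-free primer-length substrings on both
#' sides of the target, filters them on GC content, Wallace Tm, homopolymer
#' length and 3'-self/cross-complementarity, and pairs forward/reverse
#' candidates meeting product-size and Tm-difference constraints. Pairs are
#' ranked by Tm difference, then by closeness of the product size to 400 bp.
#' The reverse primer is emitted as the reverse complement of its template
#' interval.
#'
#' @param msa a `MultipleAlignment`.
#' @param target `c(start, end)` alignment columns the product must span.
#' @param reference sample id used to measure product size (default: first
#'   row).
#' @param primer_len `c(min, max)` primer length (default 18-24).
#' @param gc_range percent GC bounds (default 40-60).
#' @param tm_range Wallace Tm bounds in degrees C (default 50-62, matching a
#'   49-55 degree annealing protocol with margin).
#' @param product_range product size bounds in bp (default 150-900).
#' @param max_tm_diff maximum |Tm_f - Tm_r| (default 5).
#' @param max_homopolymer longest allowed single-base run (default 4).
#' @param max_3prime_selfcomp longest allowed complementary run involving a
#'   3'-terminal 8-mer (default 4).
#' @param max_candidates per-side cap on filtered candidates, nearest to the
#'   target first (default 200).
#' @param n_best maximum pairs returned (default 20).
#' @return data frame of primer pairs (`forward`, `reverse`, footprints in
#'   alignment columns, `product_size`, `tm_f`, `tm_r`, `gc_f`, `gc_r`).
#'   When empty, the `"filter_report"` attribute counts candidates removed
#'   by each filter.
#' @export
design_primer_pairs <- function(msa, target, reference = names(msa$seqs)[1L],
                                primer_len = c(18L, 24L),
                                gc_range = c(40, 60), tm_range = c(50, 62),
                                product_range = c(150L, 900L),
                                max_tm_diff = 5, max_homopolymer = 4L,
                                max_3prime_selfcomp = 4L,
                                max_candidates = 200L, n_best = 20L) {
  stopifnot(target[1] >= 1L, target[2] <= msa$length)
  cons <- conserved_columns(msa)
  consensus <- s2c(msa$seqs[[1L]])
  refch <- s2c(msa$seqs[[reference]])
  cum <- cumsum(refch != "-")
  report <- c(gc = 0L, tm = 0L, homopolymer = 0L, selfcomp = 0L,
              tm_diff = 0L, product_size = 0L)

  enumerate <- function(side) {
    out <- list()
    for (len in primer_len[1]:primer_len[2]) {
      starts <- seq_len(msa$length - len + 1L)
      if (side == "left") starts <- starts[starts + len - 1L < target[1]]
      else starts <- starts[starts > target[2]]
      for (s in starts) {
        e <- s + len - 1L
        if (!all(cons[s:e])) next
        template <- paste0(consensus[s:e], collapse = "")
        primer <- if (side == "left") template else revcomp(template)
        if (max_homopolymer(primer) > max_homopolymer) {
          report["homopolymer"] <<- report["homopolymer"] + 1L; next
        }
        gc <- primer_gc_pct(primer)
        if (gc < gc_range[1] || gc > gc_range[2]) {
          report["gc"] <<- report["gc"] + 1L; next
        }
        tm <- primer_tm(primer)
        if (tm < tm_range[1] || tm > tm_range[2]) {
          report["tm"] <<- report["tm"] + 1L; next
        }
        if (comp_run_3prime(primer, primer) > max_3prime_selfcomp) {
          report["selfcomp"] <<- report["selfcomp"] + 1L; next
        }
        out[[length(out) + 1L]] <- data.frame(
          primer = primer, start = s, end = e, tm = tm, gc = gc)
      }
    }
    if (length(out) == 0L) return(NULL)
    df <- do.call(rbind, out)
    dist <- if (side == "left") target[1] - df$end else df$start - target[2]
    df <- df[order(dist), , drop = FALSE]
    if (nrow(df) > max_candidates) {
      # subsample evenly across the distance range so every admissible
      # product size stays reachable
      df <- df[unique(round(seq(1, nrow(df), length.out = max_candidates))), ,
               drop = FALSE]
    }
    df
  }

  fw <- enumerate("left")
  rv <- enumerate("right")
  pairs <- list()
  if (!is.null(fw) && !is.null(rv)) {
    for (i in seq_len(nrow(fw))) {
      for (j in seq_len(nrow(rv))) {
        tmd <- abs(fw$tm[i] - rv$tm[j])
        if (tmd > max_tm_diff) { report["tm_diff"] <- report["tm_diff"] + 1L; next }
        psize <- cum[rv$end[j]] - cum[fw$start[i]] + 1L
        if (psize < product_range[1] || psize > product_range[2]) {
          report["product_size"] <- report["product_size"] + 1L; next
        }
        if (comp_run_3prime(fw$primer[i], rv$primer[j]) > max_3prime_selfcomp ||
            comp_run_3prime(rv$primer[j], fw$primer[i]) > max_3prime_selfcomp) {
          report["selfcomp"] <- report["selfcomp"] + 1L; next
        }
        pairs[[length(pairs) + 1L]] <- data.frame(
          forward = fw$primer[i], reverse = rv$primer[j],
          fwd_start = fw$start[i], fwd_end = fw$end[i],
          rev_start = rv$start[j], rev_end = rv$end[j],
          product_size = psize,
          tm_f = fw$tm[i], tm_r = rv$tm[j],
          gc_f = fw$gc[i], gc_r = rv$gc[j])
      }
    }
  }
  if (length(pairs) == 0L) {
    out <- data.frame(forward = character(), reverse = character(),
                      fwd_start = integer(), fwd_end = integer(),
                      rev_start = integer(), rev_end = integer(),
                      product_size = integer(), tm_f = numeric(),
                      tm_r = numeric(), gc_f = numeric(), gc_r = numeric())
    attr(out, "filter_report") <- report
    return(out)
  }
  out <- do.call(rbind, pairs)
  out <- out[order(abs(out$tm_f - out$tm_r), abs(out$product_size - 400)), ,
             drop = FALSE]
  rownames(out) <- NULL
  head(out, n_best)
}
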