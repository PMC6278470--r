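# Perfect-microsatellite (SSR) census, MISA-parameterized: maximal perfect
# runs of primitive 1-6 bp units, complete units only, with canonical
# strand/phase-invariant motif classes, region assignment on the
# quadripartite partition, and genic-context annotation.

#' Default MISA-style unit-count thresholds
#'
#' Minimum complete units per unit length: 8 for mononucleotides, 4 for
#' dinucleotides, 3 for tri- through hexanucleotides.
#'
#' @param mono,di,tri,tetra,penta,hexa minimum complete units.
#' @return named integer vector of length 6 (names `"1"`..`"6"`).
#' @export
ssr_thresholds <- function(mono = 8L, di = 4L, tri = 3L, tetra = 3L,
                           penta = 3L, hexa = 3L) {
  th <- c(`1` = mono, `2` = di, `3` = tri, `4` = tetra, `5` = penta,
          `6` = hexa)
  if (any(th < 2L)) stop("all thresholds must be >= 2")
  as.integer(th) |> setNames(names(th))
}

# is a motif primitive (not a whole-number repetition of a shorter unit)?
is_primitive <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L &&
        strrep(substr(motif, 1L, d), u %/% d) == motif) return(FALSE)
  }
  TRUE
}

#' Canonical motif class label
#'
#' Strand- and phase-invariant label `"X/Y"`: X is the lexicographic minimum
#' over all cyclic rotations of the motif, Y the same for its reverse
#' complement, the two printed in sorted order. Thus `T`, `A` -> `"A/T"`;
#' `AT` -> `"AT/AT"`.
#'
#' @param motif primitive repeat unit (1-6 bp).
#' @return class label string.
#' @export
canonical_motif_class <- function(motif) {
  u <- nchar(motif)
  stopifnot(u >= 1L, u <= 6L)
  if (!is_primitive(motif)) stop("motif '", motif, "' is not primitive")
  rots <- function(m) {
    k <- nchar(m)
    vapply(seq_len(k), function(i) {
      paste0(substr(m, i, k), substr(m, 1L, i - 1L))
    }, character(1))
  }
  x <- min(rots(motif))
  y <- min(rots(revcomp(motif)))
  paste(sort(c(x, y)), collapse = "/")
}

#' Scan a sequence for perfect microsatellites
#'
#' Reports every maximal perfect run of a primitive 1-6 bp unit whose number
#' of complete units meets the per-unit-length threshold. Only complete units
#' are counted: a trailing partial unit is excluded, so `size = units * unit
#' length` always. `N` breaks every run. Overlapping runs of different
#' primitive motifs are all reported; a run whose motif is a repetition of a
#' shorter unit is suppressed (it is contained in the shorter-unit run).
#' Records are sorted by start, then unit length, and numbered in that order.
#'
#' @param sequence DNA string (scanned linearly, no wrap-around; use the
#'   canonical LSC-first rotation for region-consistent coordinates).
#' @param thresholds named vector from [ssr_thresholds()].
#' @return data frame with columns `index`, `ssr_type` (`p1`..`p6`), `motif`,
#'   `motif_class`, `units`, `size`, `start`, `end`, `ssr` (display form such
#'   as `"(TGAT)3"`); possibly zero rows.
#' @export
scan_ssrs <- function(sequence, thresholds = ssr_thresholds()) {
  stopifnot(nzchar(sequence))
  n <- nchar(sequence)
  code <- seq_codes(sequence)   # N positions never match anything
  recs <- list()
  for (u in 1L:6L) {
    if (n < (thresholds[[as.character(u)]]) * u) next
    eq <- code[seq_len(n - u)] == code[(u + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    for (j in runs) {
      i <- starts[j]                       # first position of the region
      reg_len <- r$lengths[j] + u          # tandem region incl. final unit
      units <- reg_len %/% u
      if (units < thresholds[[as.character(u)]]) next
      motif <- substr(sequence, i, i + u - 1L)
      if (!is_primitive(motif)) next       # covered by the shorter unit
      size <- units * u
      recs[[length(recs) + 1L]] <- data.frame(
        ssr_type = paste0("p", u), motif = motif,
        units = units, size = size, start = i, end = i + size - 1L)
    }
  }
  if (length(recs) == 0L) {
    return(data.frame(index = integer(), ssr_type = character(),
                      motif = character(), motif_class = character(),
                      units = integer(), size = integer(),
                      start = integer(), end = integer(), ssr = character()))
  }
  df <- do.call(rbind, recs)
  df <- df[order(df$start, nchar(df$motif)), , drop = FALSE]
  df$motif_class <- vapply(df$motif, canonical_motif_class, character(1))
  df$ssr <- sprintf("(%s)%d", df$motif, df$units)
  df$index <- seq_len(nrow(df))
  rownames(df) <- NULL
  df[, c("index", "ssr_type", "motif", "motif_class", "units", "size",
         "start", "end", "ssr")]
}

#' Assign each SSR to its quadripartite region
#'
#' The region is the partition interval containing the SSR start; an SSR
#' whose end lies in a different region is flagged as junction-spanning.
#'
#' @param ssrs data frame from [scan_ssrs()] (coordinates on the canonical
#'   rotation).
#' @param partition a `QuadripartitePartition`.
#' @return `ssrs` with `region` and `spans_junction` columns added.
#' @export
assign_region <- function(ssrs, partition) {
  regions <- list(LSC = partition$lsc, IRb = partition$irb,
                  SSC = partition$ssc, IRa = partition$ira)
  locate <- function(pos) {
    for (r in names(regions)) {
      if (pos >= regions[[r]][1] && pos <= regions[[r]][2]) return(r)
    }
    NA_character_
  }
  ssrs$region <- vapply(ssrs$start, locate, character(1))
  end_region <- vapply(ssrs$end, locate, character(1))
  ssrs$spans_junction <- ssrs$region != end_region
  ssrs
}

#' Annotate SSRs with genic context
#'
#' Context is the gene name when the SSR lies wholly within a gene feature,
#' `"CNS"` (non-coding) when it overlaps no gene, and `"NAME-CNS"` when it
#' partially overlaps gene NAME (straddles a gene boundary).
#'
#' @param ssrs data frame with `start`/`end` columns.
#' @param features list of `GeneFeature` (same genome/rotation).
#' @return `ssrs` with a `context` column added.
#' @export
annotate_context <- function(ssrs, features) {
  ctx <- vapply(seq_len(nrow(ssrs)), function(i) {
    iv <- c(ssrs$start[i], ssrs$end[i])
    partial <- NA_character_
    for (f in features) {
      for (r in seq_len(nrow(f$intervals))) {
        g <- f$intervals[r, ]
        if (iv_contains(g, iv)) return(f$name)
        if (is.na(partial) && iv_overlaps(g, iv)) partial <- f$name
      }
    }
    if (!is.na(partial)) paste0(partial, "-CNS") else "CNS"
  }, character(1))
  ssrs$context <- ctx
  ssrs
}

#' Summarize SSR censuses across genomes
#'
#' @param ssr_lists named list of per-genome SSR data frames (regions and
#'   contexts optional).
#' @param length_breaks histogram bin edges for SSR size in bp.
#' @return list of data frames: `totals` (per genome), `by_type` (genome x
#'   p1..p6), `by_class` (pooled motif-class counts with percentages, 2
#'   decimals), `by_region` (when regions present), `length_hist`.
#' @export
summarize_ssrs <- function(ssr_lists,
                           length_breaks = c(0, 10, 15, 20, 30, Inf)) {
  if (length(ssr_lists) == 0L) stop("no SSR tables supplied")
  if (is.null(names(ssr_lists))) {
    names(ssr_lists) <- paste0("genome", seq_along(ssr_lists))
  }
  types <- paste0("p", 1:6)
  by_type <- t(vapply(ssr_lists, function(df) {
    vapply(types, function(t) sum(df$ssr_type == t), integer(1))
  }, integer(6)))
  totals <- data.frame(genome = names(ssr_lists),
                       n_ssr = vapply(ssr_lists, nrow, integer(1)))
  pooled <- do.call(rbind, lapply(ssr_lists, function(df) {
    df[, intersect(c("ssr_type", "motif_class", "size", "region"),
                   names(df)), drop = FALSE]
  }))
  npool <- nrow(pooled)
  cls <- if (npool) table(pooled$motif_class) else table(character())
  by_class <- data.frame(motif_class = names(cls),
                         count = as.integer(cls),
                         pct = if (npool) round(100 * as.integer(cls) / npool, 2)
                               else numeric(0))
  by_class <- by_class[order(-by_class$count), , drop = FALSE]
  rownames(by_class) <- NULL
  type_pool <- colSums(by_type)
  type_pct <- if (npool) round(100 * type_pool / npool, 2) else rep(0, 6)
  by_region <- NULL
  if (npool && "region" %in% names(pooled)) {
    reg <- table(factor(pooled$region, levels = c("LSC", "IRb", "SSC", "IRa")))
    by_region <- data.frame(region = names(reg), count = as.integer(reg))
  }
  hist <- if (npool) {
    h <- table(cut(pooled$size, breaks = length_breaks, right = TRUE))
    data.frame(bin = names(h), count = as.integer(h))
  } else data.frame(bin = character(), count = integer())
  list(totals = totals,
       by_type = data.frame(genome = rownames(by_type), by_type,
                            row.names = NULL, check.names = FALSE),
       type_pooled = data.frame(ssr_type = types,
                                count = as.integer(type_pool),
                                pct = as.numeric(type_pct)),
       by_class = by_class, by_region = by_region, length_hist = hist)
}

#' Per-record diff between two SSR tables
#'
#' Reports records present in one table but not the other, keyed on
#' (motif, units, start, end). Intended for transparent reconciliation when
#' two scans (or a scan and a published census) disagree: disagreements are
#' listed record by record, never silently absorbed.
#'
#' @param a,b SSR data frames.
#' @return data frame with column `only_in` (`"a"` or `"b"`) plus the record
#'   fields; zero rows when the tables agree.
#' @export
compare_ssr_tables <- function(a, b) {
  key <- function(df) paste(df$motif, df$units, df$start, df$end, sep = ":")
  ka <- key(a); kb <- key(b)
  cols <- c("ssr_type", "motif", "units", "size", "start", "end")
  da <- a[!(ka %in% kb), intersect(cols, names(a)), drop = FALSE]
  db <- b[!(kb %in% ka), intersect(cols, names(b)), drop = FALSE]
  out <- rbind(
    if (nrow(da)) cbind(only_in = "a", da),
    if (nrow(db)) cbind(only_in = "b", db))
  if (is.null(out)) {
    out <- cbind(only_in = character(),
                 a[0, intersect(cols, names(a)), drop = FALSE])
  }
  rownames(out) <- NULL
  out
}
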