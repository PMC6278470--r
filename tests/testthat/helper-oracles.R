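# Independent brute-force oracles and fixture generators. These deliberately
# take the slow, literal route (per-position loops, explicit recursion) so
# they share no code path with the package implementations they check.

random_seq <- function(n, gc = 0.4) {
  paste0(sample(c("A", "T", "G", "C"), n, replace = TRUE,
                prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
         collapse = "")
}

# ---- SSR oracle: test every (start, unit) pair for maximality, threshold
# and primitivity ------------------------------------------------------------
oracle_primitive <- function(m) {
  u <- nchar(m)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L) {
      unit <- substr(m, 1L, d)
      if (paste(rep(unit, u / d), collapse = "") == m) return(FALSE)
    }
  }
  TRUE
}

oracle_ssrs <- function(sequence, thresholds = c(8L, 4L, 3L, 3L, 3L, 3L)) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  eqc <- function(i, j) {
    ch[i] == ch[j] && ch[i] != "N"
  }
  out <- list()
  for (u in 1:6) {
    thr <- thresholds[u]
    i <- 1L
    while (i + u * thr - 1L <= n) {
      # region start: position i cannot be extended left with period u
      if (i > 1L && i - 1L + u <= n && eqc(i - 1L, i - 1L + u)) {
        i <- i + 1L; next
      }
      # walk the maximal period-u stretch
      j <- i
      while (j + u <= n && eqc(j, j + u)) j <- j + 1L
      reg_len <- (j - i) + u
      units <- reg_len %/% u
      if (units >= thr) {
        motif <- substr(sequence, i, i + u - 1L)
        if (!grepl("N", motif) && oracle_primitive(motif)) {
          out[[length(out) + 1L]] <- data.frame(
            motif = motif, units = units, start = i,
            end = i + units * u - 1L)
        }
      }
      i <- i + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(motif = character(), units = integer(),
                      start = integer(), end = integer()))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, nchar(df$motif)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# ---- inverted-repeat oracle: scan every alignment diagonal of the sequence
# against its reverse complement --------------------------------------------
oracle_ir <- function(sequence, min_ir_len) {
  n <- nchar(sequence)
  comp <- chartr("ACGTN", "TGCAN", sequence)
  rc <- paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  sch <- strsplit(sequence, "")[[1]]
  rch <- strsplit(rc, "")[[1]]
  best <- NULL
  for (d in (-(n - 1L)):(n - 1L)) {
    i <- max(1L, 1L + d):min(n, n + d)
    p <- i - d
    eq <- sch[i] == rch[p] & sch[i] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    for (k in which(r$values)) {
      a1 <- i[ends[k] - r$lengths[k] + 1L]
      L <- r$lengths[k]
      p1 <- a1 - d
      b2 <- n - p1 + 1L
      b1 <- b2 - L + 1L
      if (b1 <= a1 + L - 1L) {
        L <- (b2 - a1 + 1L) %/% 2L
        b1 <- b2 - L + 1L
      }
      if (L < min_ir_len || a1 + L - 1L >= b1) next
      if (is.null(best) || L > best$length ||
          (L == best$length && a1 < best$a[1])) {
        best <- list(a = c(a1, a1 + L - 1L), b = c(b1, b2), length = L)
      }
    }
  }
  best
}

# ---- global-alignment oracles ----------------------------------------------
# score over all alignments by recursion on (i, j, previous op); gap run of
# length L costs open + (L - 1) * extend
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               gap_open = -2, gap_extend = -1,
                               memo = TRUE) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  cache <- if (memo) new.env(parent = emptyenv()) else NULL
  rec <- function(i, j, prev) {
    if (i == na && j == nb) return(0)
    key <- paste0(i, ",", j, ",", prev)
    if (memo && !is.null(cache[[key]])) return(cache[[key]])
    best <- -Inf
    if (i < na && j < nb) {
      s <- if (ca[i + 1L] == cb[j + 1L] && ca[i + 1L] != "N") match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "M"))
    }
    if (i < na) {
      g <- if (prev == "U") gap_extend else gap_open
      best <- max(best, g + rec(i + 1L, j, "U"))
    }
    if (j < nb) {
      g <- if (prev == "L") gap_extend else gap_open
      best <- max(best, g + rec(i, j + 1L, "L"))
    }
    if (memo) cache[[key]] <- best
    best
  }
  rec(0L, 0L, "M")
}

# fully explicit enumeration (no memo) for very short strings, used to
# cross-check the recursive oracle itself
oracle_align_enumerate <- function(a, b, ...) {
  oracle_align_score(a, b, ..., memo = FALSE)
}

# ---- additive distance matrices from random trees (ape is the independent
# route here) ----------------------------------------------------------------
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(k) runif(k, 0.05, 1))
  tr <- ape::unroot(tr)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# shared small fixtures
labelled_panel_config <- function(...) {
  args <- utils::modifyList(
    list(n_species = 3L, samples_per_species = 10L, n_diag_snps = 3L,
         diag_indel_lengths = 6L, intraspecific_rate = 0.003),
    list(...))
  do.call(simulation_config, args)
}
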