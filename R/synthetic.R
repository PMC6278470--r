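# Seeded generators for every fixture the pipeline consumes: plastome-like
# genomes with a planted IR pair, SSRs and gene features; and labeled
# per-species sample panels with planted diagnostic events plus
# intraspecific noise that never touches diagnostic columns. Background is
# i.i.d. at a configured GC: the consuming algorithms are combinatorial and
# need controlled truth, not mutational realism.

#' Simulation configuration
#'
#' Defaults describe a small but structurally faithful world: an 8 kb LSC,
#' 3 kb IR copies and a 1.5 kb SSC (real plastomes are ~10x larger with the
#' same topology); background GC 0.37 as in Polygonaceae plastomes; 3
#' species x 10 samples with 3 private substitutions each plus one private
#' 6 bp deletion; intraspecific noise 0.002 substitutions/site.
#'
#' @param lsc_len,ir_len,ssc_len region lengths in bp.
#' @param gc background GC fraction.
#' @param n_species number of species in panels.
#' @param samples_per_species samples per species.
#' @param n_diag_snps private diagnostic substitutions per species.
#' @param diag_indel_lengths lengths (bp) of private indels, assigned to
#'   species round-robin.
#' @param diag_indel_types `"deletion"` or `"insertion"` per indel
#'   (recycled; default all deletions).
#' @param intraspecific_rate per-base substitution probability per sample at
#'   non-diagnostic positions (<= 0.05).
#' @param ssr_plants list of `list(motif =, units =, region =)` perfect SSRs
#'   to plant (region one of LSC/IRb/SSC).
#' @param gene_plants list of `list(name =, start =, end =, kind =, strand =)`
#'   features in genome coordinates, or `NULL` for a feature-free genome.
#' @return list of class `SimulationConfig`.
#' @export
simulation_config <- function(lsc_len = 8000L, ir_len = 3000L,
                              ssc_len = 1500L, gc = 0.37,
                              n_species = 3L, samples_per_species = 10L,
                              n_diag_snps = 3L,
                              diag_indel_lengths = 6L,
                              diag_indel_types = "deletion",
                              intraspecific_rate = 0.002,
                              ssr_plants = list(),
                              gene_plants = NULL) {
  stopifnot(lsc_len > 0L, ir_len > 0L, ssc_len > 0L,
            gc > 0, gc < 1,
            n_species >= 2L, samples_per_species >= 1L,
            n_diag_snps >= 0L,
            all(diag_indel_lengths >= 1L) || length(diag_indel_lengths) == 0L,
            intraspecific_rate >= 0, intraspecific_rate <= 0.05)
  for (p in ssr_plants) {
    stopifnot(!is.null(p$motif), !is.null(p$units), !is.null(p$region))
    if (!is_primitive(p$motif)) stop("planted motif not primitive: ", p$motif)
  }
  structure(list(lsc_len = as.integer(lsc_len), ir_len = as.integer(ir_len),
                 ssc_len = as.integer(ssc_len), gc = gc,
                 n_species = as.integer(n_species),
                 samples_per_species = as.integer(samples_per_species),
                 n_diag_snps = as.integer(n_diag_snps),
                 diag_indel_lengths = as.integer(diag_indel_lengths),
                 diag_indel_types = diag_indel_types,
                 intraspecific_rate = intraspecific_rate,
                 ssr_plants = ssr_plants, gene_plants = gene_plants),
            class = "SimulationConfig")
}

random_dna_chars <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

# pick a base different from all bases in `avoid`
other_base <- function(avoid) {
  choices <- setdiff(DNA_BASES, avoid)
  if (length(choices) == 0L) stop("no base available")
  choices[sample.int(length(choices), 1L)]
}

#' Simulate a plastome-like genome with a planted IR pair
#'
#' Constructs `LSC || IRb || SSC || reverse-complement(IRb)` from i.i.d.
#' background at the configured GC, plants the configured perfect SSRs at
#' recorded coordinates (with guard bases on both sides so no run extends
#' beyond its planted unit count), and attaches the configured gene
#' features. Fully deterministic given `(config, seed)`.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return list with `genome` (a `GenomeRecord`) and `truth` (list: `ir`
#'   intervals, `ssrs` data frame, `regions`).
#' @export
simulate_plastome <- function(config, seed = 1L) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(seed)
  ll <- config$lsc_len; il <- config$ir_len; sl <- config$ssc_len
  n <- ll + 2L * il + sl
  regions <- list(LSC = c(1L, ll),
                  IRb = c(ll + 1L, ll + il),
                  SSC = c(ll + il + 1L, ll + il + sl),
                  IRa = c(ll + il + sl + 1L, n))
  ch <- c(random_dna_chars(ll, config$gc),
          random_dna_chars(il, config$gc),
          random_dna_chars(sl, config$gc),
          rep("A", il))   # IRa filled after planting

  # place planted SSRs: evenly spaced slots within each region, seeded jitter
  plants <- config$ssr_plants
  truth_ssrs <- NULL
  if (length(plants)) {
    by_region <- split(seq_along(plants),
                       vapply(plants, `[[`, character(1), "region"))
    placed <- list()
    for (reg in names(by_region)) {
      if (!reg %in% c("LSC", "IRb", "SSC")) {
        stop("plant region must be LSC, IRb or SSC (IRa is the mirror copy)")
      }
      idx <- by_region[[reg]]
      r0 <- regions[[reg]][1]; rlen <- regions[[reg]][2] - r0 + 1L
      slot <- (rlen - 20L) %/% length(idx)
      for (k in seq_along(idx)) {
        p <- plants[[idx[k]]]
        u <- nchar(p$motif); size <- u * p$units
        if (slot < size + 12L) stop("planted SSRs overlap: region ", reg,
                                    " too small for ", length(idx), " plants")
        jitter <- sample.int(slot - size - 10L, 1L)
        start <- r0 + 10L + (k - 1L) * slot + jitter
        end <- start + size - 1L
        mo <- s2c(p$motif)
        ch[start:end] <- rep(mo, p$units)
        # guards: left breaks period (and any homopolymer), right likewise
        ch[start - 1L] <- other_base(c(mo[u], ch[start - 2L]))
        ch[end + 1L] <- other_base(c(mo[1L], ch[end + 2L]))
        placed[[length(placed) + 1L]] <- data.frame(
          motif = p$motif, units = p$units, size = size,
          start = start, end = end, region = reg)
      }
    }
    truth_ssrs <- do.call(rbind, placed)
  }
  # mirror IRb into IRa
  irb_seq <- c2s(ch[regions$IRb[1]:regions$IRb[2]])
  ch[regions$IRa[1]:regions$IRa[2]] <- s2c(revcomp(irb_seq))
  # scrub the single-copy flanks so the planted IR pair cannot extend by
  # chance on any rotation: extension pairs the first base of a single-copy
  # gap with its last base
  for (reg in c("SSC", "LSC")) {
    lo <- regions[[reg]][1]; hi <- regions[[reg]][2]
    comp1 <- chartr("ACGT", "TGCA", ch[hi])
    if (ch[lo] == comp1) ch[lo] <- other_base(comp1)
  }

  feats <- list()
  if (!is.null(config$gene_plants)) {
    feats <- lapply(config$gene_plants, function(g) {
      gene_feature(g$name,
                   if (is.null(g$kind)) "protein_coding" else g$kind,
                   c(g$start, g$end),
                   if (is.null(g$strand)) "+" else g$strand)
    })
  }
  genome <- genome_record("synthetic_plastome", c2s(ch), feats,
                          source = "synthetic")
  truth <- list(ir = list(a = regions$IRb, b = regions$IRa, length = il),
                ssrs = truth_ssrs, regions = regions)
  list(genome = genome, truth = truth)
}

#' Simulate a labeled per-species sample panel
#'
#' Starting from a base sequence (an amplicon, or a `GenomeRecord` whose
#' feature-free positions define the intergenic space), each species
#' receives private diagnostic substitutions and indel events at
#' well-separated intergenic positions; each sample then receives seeded
#' intraspecific substitution noise at positions disjoint from every
#' diagnostic position. Deletion boundaries are made unambiguous (the base
#' sequence is edited so the deleted segment cannot slide), keeping the
#' truth alignment unique.
#'
#' @param base a `GenomeRecord` or a DNA string.
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @param aligned if `TRUE` (default) return a gap-explicit
#'   `MultipleAlignment` (the truth alignment); if `FALSE` return ungapped
#'   sample sequences (for end-to-end tests through the aligner).
#' @return list with `panel` (`MultipleAlignment` or named character vector
#'   of ungapped sequences), `labels` (id -> species), and `truth` (list:
#'   `events` data frame with species, type, base/alignment coordinates and
#'   target allele; `noise` data frame of per-sample noise positions).
#' @export
simulate_species_panel <- function(base, config, seed = 1L, aligned = TRUE) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(seed)
  if (inherits(base, "GenomeRecord")) {
    seqch <- s2c(base$sequence)
    covered <- rep(FALSE, length(seqch))
    for (f in base$features) {
      for (r in seq_len(nrow(f$intervals))) {
        covered[f$intervals[r, 1]:f$intervals[r, 2]] <- TRUE
      }
    }
  } else {
    seqch <- s2c(toupper(base))
    covered <- rep(FALSE, length(seqch))
  }
  n <- length(seqch)
  margin <- 25L
  free <- which(!covered)
  free <- free[free > margin & free <= n - margin]

  species <- paste0("species", LETTERS[seq_len(config$n_species)])
  n_indels <- length(config$diag_indel_lengths)
  indel_types <- rep(config$diag_indel_types, length.out = max(n_indels, 1L))

  # reserve non-overlapping sites: each event blocks +/- 10 bp around itself
  taken <- rep(FALSE, n)
  reserve <- function(start, end, pad = 10L) {
    lo <- max(1L, start - pad); hi <- min(n, end + pad)
    if (any(taken[lo:hi])) return(FALSE)
    taken[lo:hi] <<- TRUE
    TRUE
  }
  pick_site <- function(width) {
    cand <- free[free + width - 1L <= max(free)]
    cand <- cand[sample.int(length(cand))]
    for (s in cand) {
      if (all(!covered[s:(s + width - 1L)]) && reserve(s, s + width - 1L)) {
        return(s)
      }
    }
    stop("requested diagnostic events exceed available intergenic space")
  }

  events <- list()
  for (si in seq_along(species)) {
    if (config$n_diag_snps > 0L) {
      for (k in seq_len(config$n_diag_snps)) {
        pos <- pick_site(1L)
        alt <- other_base(seqch[pos])
        events[[length(events) + 1L]] <- list(
          species = species[si], type = "substitution",
          base_start = pos, base_end = pos, allele = alt)
      }
    }
  }
  if (n_indels > 0L) {
    for (k in seq_len(n_indels)) {
      sp <- species[((k - 1L) %% length(species)) + 1L]
      len <- config$diag_indel_lengths[k]
      type <- indel_types[k]
      pos <- pick_site(len + 2L)
      if (type == "deletion") {
        # make boundaries unambiguous: segment cannot slide left or right
        dstart <- pos + 1L; dend <- pos + len
        seqch[dstart] <- other_base(seqch[dend + 1L])
        seqch[dstart - 1L] <- other_base(c(seqch[dend], seqch[dstart]))
        events[[length(events) + 1L]] <- list(
          species = sp, type = "deletion",
          base_start = dstart, base_end = dend,
          allele = strrep("-", len))
      } else {
        ins <- random_dna_chars(len, config$gc)
        anchor <- pos + 1L
        ins[1L] <- other_base(seqch[anchor + 1L])        # no right slide
        seqch[anchor] <- other_base(c(ins[len], ins[1L])) # no left slide
        events[[length(events) + 1L]] <- list(
          species = sp, type = "insertion",
          base_start = anchor, base_end = anchor,   # inserted AFTER anchor
          allele = c2s(ins))
      }
    }
  }

  # alignment columns: base positions plus insertion blocks
  ins_events <- Filter(function(e) e$type == "insertion", events)
  ins_after <- vapply(ins_events, function(e) e$base_start, integer(1))
  ins_len <- vapply(ins_events, function(e) nchar(e$allele), integer(1))
  # offset(p): number of insertion columns at or before base position p
  col_of <- function(p) {
    p + if (length(ins_after)) sum(ins_len[ins_after < p]) else 0L
  }
  L <- n + sum(ins_len)

  # per-species template rows (gapped, over alignment columns)
  sp_template <- list()
  for (sp in species) {
    row <- rep("-", L)
    row[vapply(seq_len(n), col_of, integer(1))] <- seqch
    for (e in events) {
      if (e$species != sp && e$type != "insertion") next
      if (e$type == "substitution" && e$species == sp) {
        row[col_of(e$base_start)] <- e$allele
      } else if (e$type == "deletion" && e$species == sp) {
        row[vapply(e$base_start:e$base_end, col_of, integer(1))] <- "-"
      } else if (e$type == "insertion") {
        cols <- col_of(e$base_start) + seq_len(nchar(e$allele))
        row[cols] <- if (e$species == sp) s2c(e$allele) else "-"
      }
    }
    sp_template[[sp]] <- row
  }

  # noise positions: any base position not reserved by an event
  noise_ok <- which(!taken)
  rows <- list(); labels <- character(0); noise_log <- list()
  for (sp in species) {
    for (s in seq_len(config$samples_per_species)) {
      id <- sprintf("%s_s%02d", sp, s)
      row <- sp_template[[sp]]
      if (config$intraspecific_rate > 0 && length(noise_ok)) {
        hit <- noise_ok[runif(length(noise_ok)) < config$intraspecific_rate]
        for (p in hit) {
          cp <- col_of(p)
          if (row[cp] == "-") next
          row[cp] <- other_base(row[cp])
        }
        if (length(hit)) {
          noise_log[[length(noise_log) + 1L]] <- data.frame(
            sample = id, base_pos = hit)
        }
      }
      rows[[id]] <- c2s(row)
      labels[id] <- sp
    }
  }

  truth_events <- do.call(rbind, lapply(events, function(e) {
    if (e$type == "insertion") {
      a1 <- col_of(e$base_start) + 1L
      a2 <- a1 + nchar(e$allele) - 1L
    } else {
      a1 <- col_of(e$base_start); a2 <- col_of(e$base_end)
    }
    data.frame(species = e$species, event_type = e$type,
               base_start = e$base_start, base_end = e$base_end,
               aln_start = a1, aln_end = a2, target_allele = e$allele)
  }))
  if (is.null(truth_events)) {
    truth_events <- data.frame(species = character(), event_type = character(),
                               base_start = integer(), base_end = integer(),
                               aln_start = integer(), aln_end = integer(),
                               target_allele = character())
  } else {
    truth_events <- truth_events[order(truth_events$aln_start), , drop = FALSE]
    rownames(truth_events) <- NULL
  }
  noise_df <- if (length(noise_log)) do.call(rbind, noise_log) else
    data.frame(sample = character(), base_pos = integer())

  gapped <- unlist(rows)
  panel <- if (aligned) {
    multiple_alignment(gapped, labels = labels)
  } else {
    vapply(gapped, degap, character(1)) |> setNames(names(gapped))
  }
  list(panel = panel, labels = labels,
       truth = list(events = truth_events, noise = noise_df))
}
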