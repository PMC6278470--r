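# diagnostic event calling, reference mapping, primer design

test_that("planted diagnostic events are recovered exactly (small sweep)", {
  set.seed(201)
  cfg <- labelled_panel_config()
  for (seed in 1:10) {
    pan <- simulate_species_panel(random_seq(500), cfg, seed = seed)
    ev <- call_diagnostic_events(pan$panel)
    core <- ev[ev$event_type != "haplotype_block", ]
    truth <- pan$truth$events
    key <- function(df) sort(paste(df$event_type, df$species, df$aln_start,
                                   df$aln_end, df$target_allele))
    expect_equal(key(core), key(truth))
    # every event re-validates its allele partition against the alignment
    m <- aln_matrix(pan$panel)
    for (i in seq_len(nrow(core))) {
      cols <- core$aln_start[i]:core$aln_end[i]
      sp_rows <- names(which(pan$labels == core$species[i]))
      oth <- setdiff(rownames(m), sp_rows)
      tstate <- paste0(m[sp_rows[1], cols], collapse = "")
      expect_equal(tstate, core$target_allele[i])
      for (r in sp_rows) {
        expect_equal(paste0(m[r, cols], collapse = ""), tstate)
      }
      for (r in oth) {
        expect_false(paste0(m[r, cols], collapse = "") == tstate)
      }
    }
  }
})

test_that("degenerate alignments produce no events or clean errors", {
  seqs <- setNames(rep("ACGTACGTAC", 6), paste0("s", 1:6))
  labels <- setNames(rep(c("A", "B", "C"), each = 2), names(seqs))
  msa <- multiple_alignment(seqs, labels = labels)
  expect_equal(nrow(call_diagnostic_events(msa)), 0L)
  expect_error(call_diagnostic_events(multiple_alignment(seqs)), "label")
  expect_error(call_diagnostic_events(msa, min_samples_per_species = 3L),
               "< 3 samples")
})

test_that("within-species disagreement disqualifies a column", {
  set.seed(202)
  # species C carries the alternative allele in only 9 of 10 samples
  base <- random_seq(60)
  alt <- base
  substr(alt, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                 substr(base, 30, 30))[1]
  seqs <- c(setNames(rep(base, 10), paste0("A", 1:10)),
            setNames(rep(base, 10), paste0("B", 1:10)),
            setNames(c(rep(alt, 9), base), paste0("C", 1:10)))
  labels <- setNames(rep(c("spA", "spB", "spC"), each = 10), names(seqs))
  ev <- call_diagnostic_events(multiple_alignment(seqs, labels = labels))
  expect_equal(nrow(ev), 0L)
  # with the 10th sample fixed too, the column is diagnostic
  seqs["C10"] <- alt
  ev2 <- call_diagnostic_events(multiple_alignment(seqs, labels = labels))
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$species, "spC")
  expect_equal(ev2$aln_start, 30L)
})

test_that("alignment columns map to reference coordinates", {
  set.seed(203)
  seqs <- c(ref = "ACGTACGTAC", alt = "ACGTACGTAC")
  msa <- multiple_alignment(seqs)
  ev <- list(aln_start = 4L, aln_end = 6L)
  m0 <- map_event_to_reference(ev, msa, "ref")
  expect_equal(c(m0$ref_start, m0$ref_end), c(4L, 6L))   # gap-free identity

  # reference with 2 gaps in columns 1-10; event at columns 11-16 -> 9-14
  g <- c(ref = paste0("AC-GT-ACGT", "AAAAAA"),
         alt = paste0("ACCGTTACGT", "AAAAAA"))
  msag <- multiple_alignment(g)
  m1 <- map_event_to_reference(list(aln_start = 11L, aln_end = 16L),
                               msag, "ref")
  expect_equal(c(m1$ref_start, m1$ref_end), c(9L, 14L))
  expect_false(m1$between)
  expect_error(map_event_to_reference(ev, msa, "nope"), "reference")

  # round-trip: mapped coordinates retrieve the target allele
  cfg <- labelled_panel_config(intraspecific_rate = 0)
  pan <- simulate_species_panel(random_seq(400), cfg, seed = 9)
  ev <- call_diagnostic_events(pan$panel)
  subs <- ev[ev$event_type == "substitution", ]
  for (i in seq_len(nrow(subs))) {
    sp_sample <- names(which(pan$labels == subs$species[i]))[1]
    mp <- map_event_to_reference(subs[i, ], pan$panel, sp_sample)
    refseq <- degap(pan$panel$seqs[[sp_sample]])
    expect_equal(substr(refseq, mp$ref_start, mp$ref_end),
                 subs$target_allele[i])
  }
})

test_that("conserved flank discovery is complete and ordered", {
  msa <- multiple_alignment(c(a = strrep("ACGT", 25),
                              b = strrep("ACGT", 25)))   # 100 conserved cols
  fl <- find_conserved_flanks(msa, target = c(41, 60), flank_len = 10)
  expect_equal(nrow(fl$left), 40 - 10 + 1)     # windows ending before col 41
  expect_equal(nrow(fl$right), 100 - 60 - 10 + 1)
  expect_equal(fl$left$distance[1], 1)         # nearest-first ordering
  expect_equal(fl$right$distance[1], 1)
  # target abutting the end: no right candidates
  fl2 <- find_conserved_flanks(msa, target = c(95, 100), flank_len = 10)
  expect_equal(nrow(fl2$right), 0L)
})

test_that("Wallace-rule Tm follows the closed form", {
  expect_equal(primer_tm(paste0(strrep("G", 10), strrep("A", 10))), 60)
  expect_equal(primer_tm(strrep("A", 20)), 40)
  expect_error(primer_tm("ACGTACG"), "shorter")
  expect_error(primer_tm("ACGTACGTN"), "non-ACGT")
})

test_that("primer pairs satisfy their filters and cover the target", {
  set.seed(55)
  cfg <- labelled_panel_config(intraspecific_rate = 0.002)
  pan <- simulate_species_panel(random_seq(700, gc = 0.5), cfg, seed = 23)
  ev <- call_diagnostic_events(pan$panel)
  del <- ev[ev$event_type == "deletion", ][1, ]
  target <- c(del$aln_start, del$aln_end)
  pp <- design_primer_pairs(pan$panel, target)
  expect_gt(nrow(pp), 0L)
  ref <- names(pan$panel$seqs)[1]
  refcum <- cumsum(strsplit(pan$panel$seqs[[ref]], "")[[1]] != "-")
  for (i in seq_len(nrow(pp))) {
    expect_lt(pp$fwd_end[i], target[1])        # product spans the target
    expect_gt(pp$rev_start[i], target[2])
    expect_lte(abs(pp$tm_f[i] - pp$tm_r[i]), 5)
    for (pr in c(pp$forward[i], pp$reverse[i])) {
      expect_gte(nchar(pr), 18); expect_lte(nchar(pr), 24)
      expect_equal(primer_tm(pr), if (pr == pp$forward[i]) pp$tm_f[i] else pp$tm_r[i])
      gc <- 100 * gc_content(pr)
      expect_gte(gc, 40); expect_lte(gc, 60)
      expect_lte(max(rle(strsplit(pr, "")[[1]])$lengths), 4)
    }
    # product size re-checked against the de-gapped reference
    expect_equal(pp$product_size[i],
                 refcum[pp$rev_end[i]] - refcum[pp$fwd_start[i]] + 1L)
    # reverse primer is the reverse complement of its template interval
    tmpl <- substr(pan$panel$seqs[[ref]], pp$rev_start[i], pp$rev_end[i])
    expect_equal(pp$reverse[i], revcomp(tmpl))
  }

  # all-A flanks fail homopolymer/GC filters and the report explains it
  polyA <- multiple_alignment(c(x = strrep("A", 120), y = strrep("A", 120)))
  empty <- design_primer_pairs(polyA, target = c(55, 60))
  expect_equal(nrow(empty), 0L)
  rep <- attr(empty, "filter_report")
  expect_gt(sum(rep), 0)
  expect_gt(rep[["homopolymer"]], 0)
})
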