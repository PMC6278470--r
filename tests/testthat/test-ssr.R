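# perfect-microsatellite scanner, motif classes, region/context annotation

test_that("threshold boundaries behave as stated", {
  r <- scan_ssrs("AAAAAAAA")
  expect_equal(nrow(r), 1L)
  expect_equal(r$ssr_type, "p1")
  expect_equal(r$motif, "A")
  expect_equal(r$units, 8L)
  expect_equal(c(r$start, r$end), c(1L, 8L))
  expect_equal(nrow(scan_ssrs("AAAAAAA")), 0L)       # 7 < 8
  expect_equal(nrow(scan_ssrs("ATATATA")), 0L)       # 3 complete AT units
  r2 <- scan_ssrs("ATATATAT")
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$units, 4L)
  expect_equal(r2$ssr_type, "p2")
  # trailing partial unit excluded: size is an exact multiple
  r3 <- scan_ssrs("TGATTGATTGATTG")
  expect_equal(r3$units, 3L)
  expect_equal(r3$size, 12L)
  # N breaks runs
  expect_equal(nrow(scan_ssrs("AAAANAAAA")), 0L)
})

test_that("motif classes are strand- and phase-invariant", {
  expect_equal(canonical_motif_class("T"), "A/T")
  expect_equal(canonical_motif_class("A"), "A/T")
  expect_equal(canonical_motif_class("AT"), "AT/AT")
  # all rotations and the reverse complement's rotations share one label
  set.seed(11)
  for (rep in 1:30) {
    u <- sample(1:6, 1)
    m <- random_seq(u)
    if (!plastidmarker:::is_primitive(m)) next
    lab <- canonical_motif_class(m)
    forms <- character(0)
    for (i in seq_len(u)) {
      rot <- paste0(substr(m, i, u), substr(m, 1, i - 1))
      forms <- c(forms, rot, revcomp(rot))
    }
    for (f in forms) expect_equal(canonical_motif_class(f), lab)
  }
  expect_equal(canonical_motif_class("GTCT"), canonical_motif_class("CTGT"))
  expect_equal(canonical_motif_class("GTCT"), canonical_motif_class("AGAC"))
  expect_error(canonical_motif_class("ATAT"), "primitive")
})

test_that("scanner equals the brute-force enumerator on random sequences", {
  set.seed(21)
  for (rep in 1:30) {
    s <- random_seq(sample(200:1000, 1), gc = runif(1, 0.25, 0.55))
    # boost repeat content so the comparison is not vacuous
    ins <- sample(c("AAAAAAAAA", "ATATATATAT", "TGATGATGA", "CCCCCCCC"), 2)
    pos <- sort(sample(50:150, 2))
    s <- paste0(substr(s, 1, pos[1]), ins[1],
                substr(s, pos[1] + 1, pos[2]), ins[2],
                substr(s, pos[2] + 1, nchar(s)))
    got <- scan_ssrs(s)[, c("motif", "units", "start", "end")]
    want <- oracle_ssrs(s)
    rownames(got) <- NULL
    expect_equal(got, want)
    # each record re-verifies its own invariant
    full <- scan_ssrs(s)
    for (i in seq_len(nrow(full))) {
      expect_equal(substr(s, full$start[i], full$end[i]),
                   strrep(full$motif[i], full$units[i]))
      expect_equal(full$size[i], full$end[i] - full$start[i] + 1L)
    }
  }
})

test_that("reverse-complement scan mirrors classes, sizes and coordinates", {
  set.seed(31)
  for (rep in 1:10) {
    s <- paste0(random_seq(300), "AAAAAAAAAA", random_seq(100),
                "TGATGATGATGAT", random_seq(200))
    n <- nchar(s)
    fwd <- scan_ssrs(s)
    rev <- scan_ssrs(revcomp(s))
    key <- function(df) sort(paste(df$motif_class, df$size))
    expect_equal(key(fwd), key(rev))
    # coordinates mirror up to the repeat phase: a region with a trailing
    # partial unit yields a complete-unit record hugging the left end in
    # each scan direction, so starts may shift by < unit length
    for (i in seq_len(nrow(rev))) {
      m_start <- n - rev$end[i] + 1L
      u <- nchar(rev$motif[i])
      match_i <- which(fwd$motif_class == rev$motif_class[i] &
                         fwd$size == rev$size[i] &
                         abs(fwd$start - m_start) < u)
      expect_length(match_i, 1L)
    }
  }
})

test_that("region assignment uses the partition and sums to the total", {
  cfg <- simulation_config(
    lsc_len = 6000, ir_len = 2000, ssc_len = 1200,
    ssr_plants = list(list(motif = "A", units = 10, region = "LSC"),
                      list(motif = "AT", units = 6, region = "IRb"),
                      list(motif = "TGA", units = 4, region = "SSC")))
  sim <- simulate_plastome(cfg, seed = 17)
  ir <- find_longest_inverted_repeat(sim$genome$sequence)
  part <- partition_quadripartite(sim$genome, ir)
  ssrs <- assign_region(scan_ssrs(sim$genome$sequence), part)
  tr <- sim$truth$ssrs
  for (i in seq_len(nrow(tr))) {
    hit <- ssrs[ssrs$start == tr$start[i] & ssrs$motif == tr$motif[i], ]
    expect_equal(hit$region, tr$region[i])
  }
  expect_equal(sum(table(ssrs$region)), nrow(ssrs))
  # a planted IRb SSR has a mirrored IRa copy
  expect_true(any(ssrs$region == "IRa" & ssrs$motif_class == "AT/AT"))
})

test_that("genic context labels distinguish gene, CNS and straddling", {
  feats <- list(gene_feature("matK", "protein_coding", c(101L, 160L)),
                gene_feature("petL", "protein_coding", c(301L, 330L)))
  # wholly inside matK; in open CNS; straddling petL's 3' boundary
  ssrs <- data.frame(start = c(101L, 161L, 326L), end = c(112L, 171L, 335L))
  out <- annotate_context(ssrs, feats)
  expect_equal(out$context, c("matK", "CNS", "petL-CNS"))
  # feature-free genome: everything is CNS
  out2 <- annotate_context(ssrs, list())
  expect_equal(unique(out2$context), "CNS")
})

test_that("summaries pool correctly and empty censuses are well-defined", {
  set.seed(603)
  s1 <- scan_ssrs(paste0(strrep("A", 10), random_seq(50), strrep("AT", 5)))
  s2 <- scan_ssrs(paste0(random_seq(40), strrep("TGA", 5)))
  s0 <- scan_ssrs(random_seq(30))     # likely empty
  sums <- summarize_ssrs(list(g1 = s1, g2 = s2, g0 = s0))
  expect_equal(sums$totals$n_ssr, c(nrow(s1), nrow(s2), nrow(s0)))
  # pooled type counts equal the sum of per-genome counts
  tp <- sums$type_pooled
  for (t in tp$ssr_type) {
    expect_equal(tp$count[tp$ssr_type == t],
                 sum(s1$ssr_type == t) + sum(s2$ssr_type == t) +
                   sum(s0$ssr_type == t))
  }
  expect_equal(sum(tp$count), sum(sums$totals$n_ssr))
  expect_error(summarize_ssrs(list()), "no SSR")
})

test_that("table comparison reports per-record differences", {
  a <- scan_ssrs(paste0(strrep("A", 10), "CG", strrep("AT", 5)))
  b <- a[-1, ]
  d <- compare_ssr_tables(a, b)
  expect_equal(nrow(d), 1L)
  expect_equal(d$only_in, "a")
  expect_equal(d$motif, a$motif[1])
  expect_equal(nrow(compare_ssr_tables(a, a)), 0L)
})
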