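# distances, neighbor joining, bootstrap, rooting, newick

test_that("p and Poisson distances follow their closed forms", {
  set.seed(301)
  a <- random_seq(40)
  msa <- multiple_alignment(c(x = a, y = a))
  d0 <- pairwise_distance(msa, model = "p")
  expect_equal(unname(d0["x", "y"]), 0)
  expect_equal(unname(pairwise_distance(msa)["x", "y"]), 0)

  # p = 0.1 over 10 columns -> -ln(0.9)
  x <- "AAAAAAAAAA"
  y <- "AAAAAAAAAC"
  m2 <- multiple_alignment(c(x = x, y = y))
  expect_equal(unname(pairwise_distance(m2, "p")["x", "y"]), 0.1)
  expect_equal(unname(pairwise_distance(m2, "poisson")["x", "y"]),
               -log(1 - 0.1), tolerance = 1e-9)
  expect_equal(round(unname(pairwise_distance(m2, "poisson")["x", "y"]), 9),
               0.105360516)

  # pairwise deletion: "AC-T" vs "ACGT" compares 3 columns only
  m3 <- multiple_alignment(c(x = "AC-T", y = "ACGT"))
  expect_equal(unname(pairwise_distance(m3, "p")["x", "y"]), 0)
  m4 <- multiple_alignment(c(x = "AC-A", y = "ACGT"))
  expect_equal(unname(pairwise_distance(m4, "p")["x", "y"]), 1 / 3)

  # no comparable columns is an error naming the pair
  m5 <- multiple_alignment(c(x = "AC--", y = "--GT", z = "ACGT"))
  expect_error(pairwise_distance(m5), "x and y")

  # poisson >= p with equality only at p = 0
  for (p in seq(0.05, 0.7, by = 0.05)) {
    expect_gt(-log(1 - p), p)
  }
  expect_identical(attr(pairwise_distance(m2, "p"), "saturated"),
                   character(0))
})

test_that("NJ recovers a known 4-taxon additive tree exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)): path distances below
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(D)
  expect_s3_class(tr, "phylo")
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_true(is_monophyletic(tr, c("C", "D")))
  # additivity: tree path lengths reproduce the input matrix
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D)

  # 3 taxa: closed-form (a+b-c)/2 pattern
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- neighbor_joining(D3)
  el <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(el[c("x", "y", "z")], c(x = 1, y = 2, z = 3))
  expect_error(neighbor_joining(D3[1:2, 1:2]), ">= 3")
})

test_that("NJ is deterministic on an equidistant matrix", {
  D <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  t1 <- neighbor_joining(D)
  for (i in 1:5) {
    expect_equal(ape::write.tree(neighbor_joining(D)), ape::write.tree(t1))
  }
  # the stated tie-break joins the smallest index pair first
  expect_true(is_monophyletic(t1, c("a", "b")))
})

test_that("NJ recovers random additive topologies (oracle: ape path sums)", {
  set.seed(61)
  for (rep in 1:15) {
    ra <- random_additive_matrix(sample(5:12, 1))
    tr <- neighbor_joining(ra$D)
    expect_equal(ape::dist.topo(ape::unroot(tr), ra$tree), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(ra$D), colnames(ra$D)],
                 ra$D, tolerance = 1e-8)
  }
})

test_that("bootstrap supports are deterministic, bounded and signal-driven", {
  # first 30 columns separate {a,b} / {c,d} / {e}; last 30 are constant, so
  # every replicate carries the same two bipartitions
  seqs <- c(a = paste0(strrep("A", 30), strrep("A", 30)),
            b = paste0(strrep("A", 30), strrep("A", 30)),
            c = paste0(strrep("C", 30), strrep("A", 30)),
            d = paste0(strrep("C", 30), strrep("A", 30)),
            e = paste0(strrep("G", 30), strrep("A", 30)))
  substr(seqs["a"], 60, 60) <- "T"   # distinguish within-clade samples
  substr(seqs["c"], 60, 60) <- "T"
  msa <- multiple_alignment(seqs)
  tr <- bootstrap_support(msa, n_replicates = 50, seed = 4)
  sup <- suppressWarnings(as.integer(tr$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_gte(sum(sup == 100), 2L)    # ab|cde and cd|abe in every replicate
  tr2 <- bootstrap_support(msa, n_replicates = 50, seed = 4)
  expect_equal(ape::write.tree(tr), ape::write.tree(tr2))  # same seed
  expect_error(bootstrap_support(multiple_alignment(c(x = "A", y = "C")),
                                 n_replicates = 5),
               "1 column")
})

test_that("outgroup rooting, monophyly and newick round-trips work", {
  set.seed(302)
  # interspecific signal (8 private sites/species) well above the noise
  # floor, as the generator contract promises for tree tests
  cfg <- labelled_panel_config(n_diag_snps = 6L, samples_per_species = 5L,
                               intraspecific_rate = 0.001)
  base <- random_seq(1000)
  pan <- simulate_species_panel(base, cfg, seed = 31)
  # outgroup derived from the pre-speciation base sequence, so it shares no
  # species-private alleles; the panel's only indel is a deletion, hence the
  # alignment columns map 1:1 onto base positions
  expect_equal(pan$panel$length, nchar(base))
  out_id <- "outgroup_1"
  ogseq <- strsplit(base, "")[[1]]
  idx <- seq(5, length(ogseq), by = 7)
  for (i in idx) ogseq[i] <- setdiff(c("A", "C", "G", "T"), ogseq[i])[1]
  seqs <- c(pan$panel$seqs,
            setNames(paste0(ogseq, collapse = ""), out_id))
  msa <- multiple_alignment(seqs)
  tree <- neighbor_joining(pairwise_distance(msa, "poisson"))
  rooted <- root_with_outgroup(tree, out_id)
  expect_true(ape::is.rooted(rooted))
  for (sp in unique(pan$labels)) {
    expect_true(is_monophyletic(tree, names(which(pan$labels == sp))))
  }
  expect_error(root_with_outgroup(tree, "missing_taxon"), "unknown")
  expect_true(is_monophyletic(tree, tree$tip.label))

  p <- withr::local_tempfile(fileext = ".nwk")
  tree$node.label <- as.character(seq_len(tree$Nnode) * 10L)
  write_newick(tree, p)
  back <- read_newick(p)
  expect_equal(ape::dist.topo(back, tree), 0, ignore_attr = TRUE)
  expect_equal(round(back$edge.length, 6), round(tree$edge.length, 6))
  expect_equal(back$node.label, tree$node.label)
})
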