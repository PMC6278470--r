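# Distance-based phylogenetics: p-distances with pairwise gap deletion,
# Poisson correction -ln(1 - p), neighbor joining with a deterministic
# tie-break, bootstrap supports, outgroup rooting and newick I/O.
#
# Trees are ape "phylo" objects throughout; ape also supplies rooting,
# monophyly queries, bipartition counting for bootstrap supports, and newick
# parsing/serialization. The NJ algorithm itself is implemented here.

# distance computation from a character matrix (rows = taxa)
dist_from_matrix <- function(m, model = c("poisson", "p")) {
  model <- match.arg(model)
  t <- nrow(m)
  ok <- matrix(m %in% DNA_BASES, nrow = t)
  d <- matrix(0, t, t, dimnames = list(rownames(m), rownames(m)))
  saturated <- character(0)
  for (i in seq_len(t - 1L)) {
    for (j in (i + 1L):t) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0L) {
        stop("no comparable columns between ", rownames(m)[i], " and ",
             rownames(m)[j])
      }
      p <- sum(m[i, comp] != m[j, comp]) / nc
      if (model == "p") {
        d[i, j] <- d[j, i] <- p
      } else {
        pairname <- paste(rownames(m)[i], rownames(m)[j], sep = "~")
        if (p >= 1) {
          warning("saturated pair (p = 1): ", pairname)
          saturated <- c(saturated, pairname)
          d[i, j] <- d[j, i] <- Inf
        } else {
          if (p >= 0.75) saturated <- c(saturated, pairname)
          d[i, j] <- d[j, i] <- -log(1 - p)
        }
      }
    }
  }
  attr(d, "saturated") <- saturated
  d
}

#' Pairwise distance matrix from a multiple alignment
#'
#' For each pair, comparable columns are those where both rows carry an
#' unambiguous base (`A,C,G,T`); gaps and `N` are excluded pair-by-pair
#' (pairwise deletion). `p` is the mismatch proportion over comparable
#' columns; the Poisson correction returns `-ln(1 - p)`. Pairs with
#' `p >= 0.75` are recorded in the `"saturated"` attribute (near-saturation);
#' `p = 1` yields `Inf` with a warning, never a silent truncation.
#'
#' @param msa a `MultipleAlignment`.
#' @param model `"poisson"` (default) or `"p"`.
#' @return symmetric numeric matrix with taxa dimnames, zero diagonal, and a
#'   `"saturated"` attribute listing flagged pairs.
#' @export
pairwise_distance <- function(msa, model = c("poisson", "p")) {
  stopifnot(inherits(msa, "MultipleAlignment"), length(msa$seqs) >= 2L)
  dist_from_matrix(aln_matrix(msa), model = match.arg(model))
}

# Core NJ engine. Returns the successive joins (pairs of node ids; leaves
# are 1..n, new internal nodes n+1, n+2, ...) together with the newick
# string. Tie-break on the Q criterion: smallest (i, j) node-id pair.
nj_engine <- function(D) {
  n <- nrow(D)
  stopifnot(n >= 3L, isTRUE(all.equal(D, t(D))), all(diag(D) == 0))
  taxa <- rownames(D)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
  labels <- taxa                 # newick fragment per active node
  ids <- seq_len(n)              # node ids of active rows
  joins <- list()
  negatives <- numeric(0)
  clamp <- function(x) {
    if (x < 0) negatives <<- c(negatives, x)
    max(x, 0)
  }
  Dm <- D
  while (length(ids) > 3L) {
    na <- length(ids)
    r <- rowSums(Dm)
    Q <- (na - 2) * Dm - outer(r, r, `+`)
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    # smallest (i, j) node-id pair among minima
    ordk <- order(ids[best[, 1]], ids[best[, 2]])
    i <- best[ordk[1], 1]; j <- best[ordk[1], 2]
    dij <- Dm[i, j]
    bi <- clamp(dij / 2 + (r[i] - r[j]) / (2 * (na - 2)))
    bj <- clamp(dij - (dij / 2 + (r[i] - r[j]) / (2 * (na - 2))))
    newlab <- sprintf("(%s:%.10g,%s:%.10g)", labels[i], bi, labels[j], bj)
    joins[[length(joins) + 1L]] <- c(ids[i], ids[j])
    dnew <- (Dm[i, ] + Dm[j, ] - dij) / 2
    keep <- setdiff(seq_len(na), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    labels <- c(labels[keep], newlab)
    ids <- c(ids[keep], n + length(joins))
  }
  if (length(ids) == 3L) {
    dxy <- Dm[1, 2]; dxz <- Dm[1, 3]; dyz <- Dm[2, 3]
    a <- clamp((dxy + dxz - dyz) / 2)
    b <- clamp((dxy + dyz - dxz) / 2)
    cc <- clamp((dxz + dyz - dxy) / 2)
    newick <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                      labels[1], a, labels[2], b, labels[3], cc)
  } else {
    stop("neighbor_joining needs >= 3 taxa")
  }
  list(joins = joins, newick = newick, negatives = negatives)
}

# join order only (guide trees); ids as in nj_engine
nj_join_order <- function(D) nj_engine(D)$joins

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ (Saitou-Nei Q criterion, canonical branch-length and matrix
#' reduction formulas). Ties on the Q criterion break toward the smallest
#' (i, j) node-id pair, so the result is deterministic. Negative branch
#' lengths are clamped to zero; the raw values are kept in the tree's
#' `"negative_branch_lengths"` attribute. The returned tree is unrooted with
#' a root trifurcation.
#'
#' @param D symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return an [ape::phylo] tree.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("neighbor_joining needs >= 3 taxa")
  eng <- nj_engine(D)
  tr <- ape::read.tree(text = eng$newick)
  attr(tr, "negative_branch_lengths") <- eng$negatives
  tr
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement `n_replicates` times
#' (seeded), rebuilds the NJ tree per replicate, and annotates each internal
#' edge of the full-data tree with the percentage of replicates containing
#' the same leaf bipartition.
#'
#' @param msa a `MultipleAlignment` (>= 2 columns).
#' @param model distance model, see [pairwise_distance()].
#' @param n_replicates number of bootstrap replicates (>= 1; the classical
#'   default is 1000).
#' @param seed integer seed controlling resampling.
#' @return the NJ tree with integer percentage supports in `node.label`.
#' @export
bootstrap_support <- function(msa, model = "poisson", n_replicates = 1000L,
                              seed = 1L) {
  stopifnot(n_replicates >= 1L)
  if (msa$length < 2L) stop("alignment of 1 column cannot be resampled")
  m <- aln_matrix(msa)
  main <- neighbor_joining(dist_from_matrix(m, model))
  set.seed(seed)
  boots <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    idx <- sample.int(ncol(m), ncol(m), replace = TRUE)
    boots[[r]] <- neighbor_joining(dist_from_matrix(m[, idx, drop = FALSE],
                                                    model))
  }
  class(boots) <- "multiPhylo"
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  main$node.label <- as.character(round(100 * counts / n_replicates))
  main
}

#' Root a tree on an outgroup
#'
#' @param tree an `ape::phylo` tree.
#' @param taxon outgroup leaf name (must be present).
#' @return rooted tree.
#' @export
root_with_outgroup <- function(tree, taxon) {
  if (!taxon %in% tree$tip.label) stop("unknown taxon: ", taxon)
  ape::root(tree, outgroup = taxon, resolve.root = TRUE)
}

#' Are the named taxa monophyletic?
#'
#' True when some edge of the (unrooted) tree induces a bipartition isolating
#' exactly the named taxa.
#'
#' @param tree an `ape::phylo` tree.
#' @param taxa character vector of leaf names.
#' @return logical scalar.
#' @export
is_monophyletic <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing)) stop("unknown taxon: ", paste(missing, collapse = ", "))
  if (setequal(taxa, tree$tip.label) || length(taxa) == 1L) return(TRUE)
  want <- sort(match(unique(taxa), tree$tip.label))
  comp <- sort(setdiff(seq_along(tree$tip.label), want))
  # every edge bipartition, from the clades of the (arbitrarily rooted)
  # representation; a group is monophyletic on an unrooted tree when either
  # side of some edge equals it
  for (cl in ape::prop.part(tree)) {
    s <- sort(cl)
    if (identical(s, want) || identical(s, comp)) return(TRUE)
  }
  FALSE
}

#' Write / read newick
#'
#' Branch lengths and integer supports (node labels) are preserved.
#'
#' @param tree an `ape::phylo` tree.
#' @param path file path.
#' @return `write_newick`: `path` invisibly; `read_newick`: a tree.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
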