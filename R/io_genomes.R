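# Genome/feature data model and flat-file I/O.
#
# Coordinates are 1-based inclusive everywhere in user-facing structures;
# only the BED writer converts (see write_bed). Features whose GenBank
# location wraps the origin are split into two intervals and flagged.

#' Construct a gene feature
#'
#' @param name gene symbol.
#' @param kind one of `protein_coding`, `tRNA`, `rRNA`, `other`.
#' @param intervals integer matrix with columns `start`, `end` (1-based
#'   inclusive), one row per exon/segment.
#' @param strand `"+"` or `"-"`.
#' @param wraps logical; `TRUE` when the feature crossed the origin and was
#'   split into two intervals.
#' @return object of class `GeneFeature`.
#' @export
gene_feature <- function(name, kind = "other",
                         intervals, strand = "+", wraps = FALSE) {
  if (is.vector(intervals) && length(intervals) == 2L) {
    intervals <- matrix(as.integer(intervals), ncol = 2L)
  }
  intervals <- matrix(as.integer(intervals), ncol = 2L,
                      dimnames = list(NULL, c("start", "end")))
  stopifnot(nrow(intervals) >= 1L,
            all(intervals[, 1L] <= intervals[, 2L]),
            kind %in% c("protein_coding", "tRNA", "rRNA", "other"),
            strand %in% c("+", "-"))
  structure(list(name = name, kind = kind, intervals = intervals,
                 strand = strand, wraps = isTRUE(wraps)),
            class = "GeneFeature")
}

#' Construct a genome record
#'
#' @param id accession or name.
#' @param sequence DNA string; uppercased, `U` normalized to `T`, ambiguity
#'   letters other than `N` mapped to `N` (with a warning giving the count).
#' @param features list of [gene_feature()] objects. Features with intervals
#'   outside `[1, length]` are dropped with a warning.
#' @param source provenance string (file path or `"synthetic"`).
#' @return object of class `GenomeRecord` with fields `id`, `sequence`,
#'   `length`, `features`, `source`.
#' @export
genome_record <- function(id, sequence, features = list(), source = "synthetic") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  norm <- normalize_dna(sequence)
  if (norm$n_mapped > 0L) {
    warning(norm$n_mapped, " ambiguity letter(s) mapped to N in record ", id)
  }
  n <- nchar(norm$sequence)
  if (n == 0L) stop("zero-length sequence for record ", id)
  keep <- vapply(features, function(f) {
    ok <- all(f$intervals[, 1L] >= 1L) && all(f$intervals[, 2L] <= n)
    if (!ok) warning("feature ", f$name, " outside sequence [1, ", n,
                     "]; dropped")
    ok
  }, logical(1))
  structure(list(id = id, sequence = norm$sequence, length = n,
                 features = features[keep], source = source),
            class = "GenomeRecord")
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat("GenomeRecord", x$id, "-", x$length, "bp,",
      length(x$features), "features (source:", paste0(x$source, ")"), "\n")
  invisible(x)
}

# ---- GenBank flat file ------------------------------------------------------

# Parse a GenBank location string into (intervals matrix, strand, wraps).
# Handles a..b, single positions, <,> partial markers, complement(...),
# join(...)/order(...) and origin-wrapping joins (last..n followed by 1..).
parse_gb_location <- function(loc, seq_len = NA_integer_) {
  strand <- "+"
  s <- gsub("[<>[:space:]]", "", loc)
  if (grepl("^complement\\(", s)) {
    strand <- "-"
    s <- sub("^complement\\((.*)\\)$", "\\1", s)
  }
  s <- sub("^(join|order)\\((.*)\\)$", "\\2", s)
  # strip a remaining complement() around individual spans (rare); strand
  # stays the outer call's
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  parts <- sub("^complement\\((.*)\\)$", "\\1", parts)
  iv <- t(vapply(parts, function(p) {
    if (grepl("\\.\\.", p)) {
      as.integer(strsplit(p, "..", fixed = TRUE)[[1]][c(1, 2)])
    } else {
      rep(as.integer(p), 2L)
    }
  }, integer(2)))
  dimnames(iv) <- list(NULL, c("start", "end"))
  wraps <- FALSE
  if (nrow(iv) >= 2L && !is.na(seq_len)) {
    # origin-wrapping join: a segment ending at seq_len followed by one
    # starting at 1
    for (k in seq_len(nrow(iv) - 1L)) {
      if (iv[k, "end"] == seq_len && iv[k + 1L, "start"] == 1L) wraps <- TRUE
    }
  }
  list(intervals = iv, strand = strand, wraps = wraps)
}

#' Read a GenBank flat file
#'
#' Parses the LOCUS/FEATURES/ORIGIN blocks of a single-record GenBank flat
#' file into a [genome_record()]. Features of type `gene`, `tRNA`, `rRNA`
#' and `CDS` are extracted; the returned feature list contains one entry per
#' `gene` feature (or per typed feature when no `gene` keys exist), with
#' `kind` inferred from a same-name `CDS`/`tRNA`/`rRNA` feature.
#'
#' @param path path to a GenBank flat file.
#' @return a `GenomeRecord`.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("GenBank format error: empty file ", path)

  org <- grep("^ORIGIN", lines)
  if (length(org) == 0L) {
    stop("GenBank format error: no ORIGIN sequence block in ", path)
  }
  org <- org[1L]
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[1L] else length(lines) + 1L
  seq_lines <- lines[seq(org + 1L, endrec - 1L)]
  sequence <- gsub("[^A-Za-z]", "", paste0(seq_lines, collapse = ""))
  if (nchar(sequence) == 0L) {
    stop("GenBank format error: zero-length sequence in ", path)
  }
  n <- nchar(sequence)

  id <- NA_character_
  acc <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc)) id <- strsplit(trimws(acc[1L]), "[[:space:]]+")[[1]][2L]
  if (is.na(id) || !nzchar(id)) {
    loc <- grep("^LOCUS", lines, value = TRUE)
    if (length(loc)) id <- strsplit(trimws(loc[1L]), "[[:space:]]+")[[1]][2L]
  }
  if (is.na(id)) id <- basename(path)

  # feature table: entries start at indent 5 with a key; continuation and
  # qualifier lines are indented 21
  fstart <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fstart)) {
    block <- lines[seq(fstart[1L] + 1L, org - 1L)]
    keyline <- grepl("^ {5}[A-Za-z0-9_'-]+ +", block)
    idx <- which(keyline)
    raw <- lapply(seq_along(idx), function(k) {
      from <- idx[k]
      to <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
      entry <- block[from:to]
      key <- sub("^ {5}([A-Za-z0-9_'-]+) +.*$", "\\1", entry[1L])
      rest <- sub("^ {5}[A-Za-z0-9_'-]+ +", "", entry[1L])
      body <- trimws(entry[-1L])
      # location may continue over lines until the first qualifier
      qual_at <- grep("^/", body)
      loc_extra <- if (length(qual_at)) head(body, qual_at[1L] - 1L) else body
      loc <- paste0(c(rest, loc_extra), collapse = "")
      quals <- if (length(qual_at)) body[qual_at[1L]:length(body)] else character()
      gene <- sub('^/gene="?([^"]*)"?$', "\\1",
                  grep("^/gene=", quals, value = TRUE))
      list(key = key, loc = loc,
           gene = if (length(gene)) gene[1L] else NA_character_)
    })
    keep_keys <- c("gene", "tRNA", "rRNA", "CDS")
    raw <- Filter(function(r) r$key %in% keep_keys, raw)
    kind_of <- c(CDS = "protein_coding", tRNA = "tRNA", rRNA = "rRNA",
                 gene = "other")
    gene_names <- vapply(raw, function(r) r$gene, character(1))
    keys <- vapply(raw, function(r) r$key, character(1))
    has_gene_key <- any(keys == "gene")
    use <- if (has_gene_key) which(keys == "gene") else seq_along(raw)
    feats <- lapply(use, function(i) {
      r <- raw[[i]]
      pl <- tryCatch(parse_gb_location(r$loc, n), error = function(e) NULL)
      if (is.null(pl)) {
        warning("unparseable location '", r$loc, "' for feature ", r$gene,
                "; dropped")
        return(NULL)
      }
      kind <- kind_of[[r$key]]
      if (r$key == "gene" && !is.na(r$gene)) {
        typed <- keys[gene_names == r$gene & keys != "gene"]
        if (length(typed)) kind <- kind_of[[typed[1L]]]
      }
      nm <- if (!is.na(r$gene)) r$gene else paste0(r$key, "_", i)
      gene_feature(nm, kind, pl$intervals, pl$strand, pl$wraps)
    })
    feats <- Filter(Negate(is.null), feats)
  }
  genome_record(id, sequence, feats, source = path)
}

# ---- FASTA ------------------------------------------------------------------

#' Read a FASTA file
#'
#' @param path FASTA path.
#' @return order-preserving named list of sequences; names are the first
#'   whitespace-delimited token of each header. Non-`ACGTN` letters are
#'   mapped to `N` with a warning.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  }
  seqs <- as.character(set)
  mapped <- 0L
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L) stop("zero-length sequence for id ", ids[i])
    norm <- normalize_dna(seqs[i])
    mapped <- mapped + norm$n_mapped
    out[[i]] <- norm$sequence
  }
  if (mapped > 0L) warning(mapped, " non-ACGTN letter(s) mapped to N")
  names(out) <- ids
  out
}

#' Write sequences as FASTA (60-column wrap)
#'
#' @param records named list or named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (length(records) == 0L) stop("no records to write")
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    stop("all records must be named")
  }
  set <- Biostrings::BStringSet(unlist(records))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# gapped FASTA: same reader, but '-' must survive normalization
#' Read an aligned (gapped) FASTA into a [multiple_alignment()]
#'
#' All-gap columns are removed with a message. `labels`, when given, is a
#' named character vector mapping sample id to species name.
#'
#' @param path aligned FASTA path.
#' @param labels optional named character vector (id -> species).
#' @return a `MultipleAlignment`.
#' @export
read_alignment <- function(path, labels = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  multiple_alignment(seqs, labels = labels, drop_allgap = TRUE)
}
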