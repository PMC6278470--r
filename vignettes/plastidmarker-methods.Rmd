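---
title: "Methods and design notes: plastome structure, SSR census, diagnostic markers"
author: "plastidmarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidmarker)
```

This vignette is the package's own account of what it computes, which
assumptions each step makes, and where the design was genuinely open. It
states no empirical result that the test suite does not itself compute.

## The analytical problem

Plastomes of congeneric plants are highly similar (>95 % identity), circular
molecules of 120–170 kb with a conserved quadripartite architecture: a large
single-copy region (LSC), a small single-copy region (SSC), and two
identical inverted-repeat copies (IRa, IRb) separating them. Species
discrimination therefore rests on a small set of informative differences —
microsatellite length variation, divergent intergenic spacers, and fixed
substitutions or indels — that this package locates and turns into
PCR-assayable markers.

## Quadripartite structure detection

The IR pair is detected from sequence alone. All k-mers (default k = 21) of
the genome are matched exactly against its reverse complement; each match
anchors a diagonal, and the first and last anchor per diagonal are extended
bidirectionally, optionally tolerating mismatches while the running mismatch
fraction stays below `max_mismatch_frac`. The maximal pair wins; equal
lengths break toward the smaller left-copy start.

* **`min_ir_len` = 1000 bp.** Real plastome IRs are 10–30 kb; the floor only
  suppresses chance palindromes. k = 21 is specific at 161 kb scale
  (expected random hits ≈ n²/4²¹ ≪ 1) and cheap to index.
* **`max_mismatch_frac` = 0.** Plastome IR copies are typically perfectly
  identical; relaxation is available but off by default.
* The two single-copy gaps on the circle are labeled by length — the longer
  is the LSC. A tie (never observed in practice) breaks toward the gap that
  follows the first IR copy being the SSC. Reporting uses the canonical
  LSC-first rotation; input coordinates live in the partition's
  `input_coords` provenance field, and `rotate_genome()` applies the
  rotation to sequence and features (origin-crossing features are split and
  flagged).
* GC content is (G+C)/(A+C+G+T) with `N` excluded from both numerator and
  denominator, quoted at one decimal in summaries. Region sizes are
  *detected*, not read from annotation; if a detected junction ever
  disagrees with a published size, the junction coordinates should be
  reported rather than silently matched.

## SSR census

`scan_ssrs()` reports every maximal perfect run of a primitive 1–6 bp unit
whose complete-unit count meets the per-unit-length threshold (defaults
8, 4, 3, 3, 3, 3 — the standard MISA parameterization for plastomes).
Decisions worth stating:

* **Complete units only.** A trailing partial unit is excluded, so
  `size = units × unit length` always; this matches the convention evident
  in published MISA tables, where all sizes are exact multiples.
* **Primitivity.** A run whose motif is a whole-number repetition of a
  shorter unit (e.g. `ATAT`) is suppressed — it is already contained in the
  shorter unit's run. Overlapping runs of *different* primitive motifs are
  all reported.
* **`N` breaks every run** (implemented by giving each `N` a unique
  comparison code so it matches nothing, not even another `N`).
* Motif classes are canonical labels `X/Y` with X the lexicographic minimum
  over cyclic rotations of the motif and Y the same for its reverse
  complement, printed sorted — invariant to strand and phase, so `T` runs
  and `A` runs both count as `A/T`.
* Both IR copies are scanned; no deduplication of the repeated region, so a
  repeat planted in IRb also appears mirrored in IRa.
* The mononucleotide threshold stays at 8 even though published tables often
  display only records >10 bp; display filtering is a reporting option
  (`--min-size`), never a scan parameter.
* Region assignment uses the partition interval containing the SSR *start*;
  junction-spanning records are flagged. Context is the gene name when the
  record lies wholly inside a gene feature, `CNS` when it overlaps none, and
  `NAME-CNS` when it straddles a boundary.

Published per-genome totals for this kind of census are known to be
internally inconsistent with the corresponding per-record tables; the
package therefore ships `compare_ssr_tables()`, which reconciles two
censuses record by record instead of absorbing differences into totals.

## Alignment and identity profiling

Pairwise alignment is global affine-gap (Gotoh) with defaults match 1,
mismatch −1, gap open −2, gap extend −1 — neutral for closely related
sequences. A gap run of length L costs `open + (L−1)·extend`. Traceback ties
break deterministically: diagonal, then up (gap in the second sequence),
then left. The progressive multiple aligner builds a guide order by neighbor
joining on 3-mer frequency distances and merges groups by affine
profile–profile alignment; its intended scale is amplicon panels (≤ ~50
sequences × ~5 kb). Whole-plastome alignments are out of scale by design:
import an externally computed aligned FASTA via `read_alignment()` instead.

The identity profile scores a window as the fraction of its columns that
are gap-free, `N`-free and uniform across all samples — any gap or `N`
makes a column non-identical, which is conservative in the right direction
for marker discovery. Window/step default to 200/50 columns, enough to
resolve the few-hundred-bp spacers where inter-species divergence
concentrates; the published comparisons this emulates do not state their
window settings, so these defaults are ours and are recorded in output
metadata. Low-identity windows (below a 90 % default threshold) are merged
into candidate intervals ranked by mean identity.

## Diagnostic event calling

For a column *c* and species *S*, *S* is column-diagnostic iff (i) all *S*
samples carry the same state at *c*, (ii) no sample of any other species
carries that state, and (iii) for substitutions, every state involved is an
unambiguous base — a gap or `N` anywhere in the column disqualifies it.
Indels are maximal runs of columns where all *S* samples are gapped and all
others are not (deletion in *S*), or the converse (insertion in *S*, with
the inserted bases additionally required to be fixed within *S*).

* Within-species fixation (rule i) is required because diagnostic screening
  panels are designed to establish species-constant sites; a
  frequency-threshold relaxation would be a config extension, deliberately
  not a default.
* Other species need *not* agree among themselves — they must only differ
  from the target allele; two substitutions can jointly diagnose a species.
* Runs of consecutive diagnostic substitution columns stay reported
  per-column (keeping the core rule column-local and testable) with an
  additional merged `haplotype_block` convenience row.
* `map_event_to_reference()` converts alignment columns to 1-based
  positions on a de-gapped reference sample; an event the reference is
  gapped across maps to the flanking pair `(left, left+1)` flagged
  `between = TRUE`.

## Primer design

Candidates are primer-length (18–24 nt) substrings of 100 %-conserved,
gap-free alignment stretches flanking the target, filtered on GC 40–60 %,
Wallace-rule Tm 50–62 °C (the deterministic `2(A+T) + 4(G+C)` estimate —
adequate at these lengths and chosen over nearest-neighbor models for
reproducibility; the window brackets a typical 49–55 °C annealing protocol),
homopolymer ≤ 4, and longest complementary run involving a 3′-terminal
8-mer ≤ 4 against both self and partner. Pairs must bracket the target with
a product of 150–900 bp on the de-gapped reference and |ΔTm| ≤ 5 °C; ranking
is by ΔTm, then product-size closeness to 400 bp. When every candidate dies
in a filter, the empty result carries a `filter_report` attribute counting
eliminations per filter. Candidate lists larger than `max_candidates` are
subsampled evenly across the distance range so that every admissible
product size stays reachable. No in-silico PCR or secondary-structure
thermodynamics — deliberately out of scope.

## Distances, trees, supports

Distances use pairwise deletion: for each pair, only columns where both
rows carry `A/C/G/T` are compared; `p` is the mismatch proportion and the
Poisson correction is `d = −ln(1 − p)`. The phrase "Poisson model" for
nucleotide data is unusual — it is interpreted here as the Poisson-corrected
distance applied to nucleotide p-distances, which is the correction of that
name in standard phylogenetics software. Saturation is surfaced, not
hidden: pairs with p ≥ 0.75 are listed in the matrix's `saturated`
attribute, and p = 1 yields `Inf` with a warning.

Neighbor joining is the canonical Q-criterion algorithm with the standard
branch-length and reduction formulas. Ties on Q break toward the smallest
node-id pair, making the output deterministic; negative branch lengths are
clamped to zero with raw values kept in an attribute. Bootstrap resamples
columns with replacement under a caller-supplied seed, and supports are the
percentage of replicate trees containing each bipartition of the full-data
tree (counted via `ape::prop.clades`). Rooting, monophyly queries and
newick I/O operate on `ape::phylo` objects; monophyly is defined on the
unrooted tree — a group is monophyletic iff some edge bipartition isolates
exactly that group.

## The synthetic world

The generator's defaults describe one fixed world, chosen once:

| parameter | default | rationale |
|---|---|---|
| LSC / IR / SSC | 8000 / 3000 / 1500 bp | same topology as a real plastome at ~10× reduction, keeping tests fast |
| background GC | 0.37 | plastome-typical |
| species × samples | 3 × 10 | a three-species screening panel |
| diagnostic SNPs/species | 3 | amplicon-scale marker density |
| diagnostic indel | one 6 bp deletion | the classic private-deletion marker |
| intraspecific noise | 0.002 subs/site | within the ≤0.5 % regime diagnostic screening assumes |

Background is i.i.d. — the consuming algorithms are combinatorial and need
controlled truth, not mutational realism. Planted SSRs get guard bases on
both sides so no run extends past its recorded unit count; single-copy
flank bases are scrubbed so the planted IR cannot extend by chance
complementarity; deletion boundaries are edited so the deleted segment
cannot slide in an alignment (unique gap placement); and per-sample noise
positions are drawn disjointly from every diagnostic position, as the truth
table records. Consequently a green planted-recovery test establishes
algorithmic correctness on unambiguous inputs — it does **not** establish
robustness to alignment ambiguity, heterotachy, or the annotation errors of
real records, which is why the GenBank-backed worked examples remain a
documented (network-requiring) workflow rather than an offline test.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere except the BED/VCF-style
  writers, which convert at the boundary.
* Ambiguity letters other than `N` normalize to `N` with a warning count;
  the diagnostic caller treats `N` as unknown-and-disqualifying.
* Zero comparable columns between a pair of rows is an error naming the
  pair; an alignment of one column cannot be bootstrapped.
* Adjacent IR copies (zero-length single-copy gap) and overlapping copies
  are rejected as degenerate rather than silently partitioned.
* All randomness — generators, bootstrap, CLI — flows through explicit
  integer seeds; two runs with the same (config, seed) are byte-identical.

## Known limitations

* The progressive aligner is a simple profile merger; for divergent or
  long sequences, import a MAFFT/ClustalW alignment instead.
* Wallace Tm ignores salt and nearest-neighbor effects; fine for ranking
  18–24-mers, not for absolute Tm prediction.
* Genome-scale tree reproduction (dozens of plastomes) is a documented
  workflow, not an offline test — it requires downloading the accessions
  and a genome-scale alignment.
* Gene-count bookkeeping from annotations (copies vs distinct names) is
  convention-dependent and deliberately not reproduced.
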