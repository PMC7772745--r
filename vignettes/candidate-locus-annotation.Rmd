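---
title: "Annotating candidate loci with genes and QTLs, and testing enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating candidate loci with genes and QTLs, and testing enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lociqtl)
```

## The problem

High-throughput genomic analyses in livestock — GWAS, RNA-seq, runs of
homozygosity, CNV scans — produce candidate markers or intervals that must be
placed in biological context: which genes do they hit, which previously
reported QTLs do they revisit, and is any trait represented more often than
the structure of the reference database would predict? `lociqtl` implements
that post-processing pipeline as data-frame-in, tibble-out functions that
chain with the pipe, plus plot builders for each result type.

Two reference formats are supported as inputs: Ensembl-style GTF for genes
(`key "value";` attributes) and the GFF dialect used by Animal QTLdb for
QTL records (`Chr.N` sequence names, `key=value;` attributes with
percent-encoded trait names, and a feature-type column that encodes the QTL
class, e.g. `Reproduction_QTL`). Candidate tables are plain delimited text
with either `(CHR, BP)` for markers or `(CHR, BP1, BP2)` for intervals; any
further columns (study, breed, model...) are carried through every
downstream result, which is what makes multi-study comparisons a one-liner.

## Annotation model

All coordinates are treated as 1-based inclusive, the convention both input
formats already use. A candidate interval is widened by a flank `window`
(base pairs, applied upstream and downstream, clipped at position 1) and
intersected with every database record on the same normalized chromosome
(`chr5`, `Chr.5` and `5` all compare equal). Overlap means at least one
shared base on closed intervals — a feature that merely touches the widened
boundary counts — and strand is ignored, since SNPs and QTL records are
strandless. Every overlapping (candidate, feature) pair becomes one output
row; candidates with no overlap appear only in the hit-count summary, so the
row count of the result is exactly the sum of per-candidate hit counts.

`window` has **no default**. Published analyses use flanks anywhere from
50 kb to several hundred kb for the same kind of data, and the choice changes
every downstream count, so it must be an explicit, reported parameter of the
analysis rather than a silent package default.

Two implementations of the join ship deliberately: `annotate_loci()` uses an
interval index (GenomicRanges), and `brute_force_overlap()` is a plain
linear scan with the identical contract. The scan exists as an independent
oracle — the test suite checks the two against each other on randomized
inputs — and is also a readable statement of the join semantics.

## Group comparison

`overlap_among_groups()` deduplicates IDs within each group before
intersecting, so a gene annotated by many markers of one study counts once.
The percentage matrix is intentionally asymmetric: cell (A, B) is the share
of *A's* records also found in B, so a small group nested in a large one
reads 100% in one direction and much less in the other. The identities
`counts(A,B) = counts(B,A)` and `percents(A,B)·|A| = 100·counts(A,B)` hold
exactly and are enforced by tests. Percentages are kept at full precision
internally and formatted to two decimals only in the combined display
matrix.

## The enrichment test

QTL databases accumulate records where research effort concentrates; raw
composition of an annotation therefore mostly restates the database. The
enrichment question is conditional: *given* the database's trait mix, is the
observed count for a trait among the annotated records larger than expected
when drawing the same number of records at random? That is the upper-tail
hypergeometric probability `P(X >= k)` with population `N`, successes `K`
and draws `n`, applied per trait (or per QTL class) either genome-wide or
chromosome-wide, optionally restricted to a chromosome subset.

Numerical choices:

* the tail is summed in log space from `lchoose` terms with a log-sum-exp
  reduction. This is not cosmetic — realistic inputs produce p-values at the
  1e-171 scale and beyond 1e-300, where naive summation underflows to 0;
* counting deduplicates annotated records by database record ID within
  scope; without that, several markers hitting one record would push `k`
  above `K` and outside the model's support;
* only traits observed at least once (`k >= 1`) are tested. Untestable
  zero rows would only inflate the correction family;
* the multiple-testing family `m` is exactly the number of emitted tests,
  recorded in the result's metadata (`glance()`), with Benjamini–Hochberg as
  the default because discovery-rate control is the convention for this
  kind of screen. Rows sort by ascending p, ties broken by trait name;
* a Monte Carlo cross-check (`permutations > 0`) re-estimates each tail by
  simulating random draws from the scoped database. It is a verification
  device for unusual inputs, never the primary method — the analytic tail
  is exact.

The *richness factor* `k/K` reported per row (and used as the bubble-plot
x-axis) is the fraction of a trait's database records captured by the
candidate regions; together with `-log10 p` (color) and `k` (bubble area)
it summarises each test's effect size, significance and support.

## Synthetic data: what it emulates and what it does not

`fixture_spec()` / `generate_fixture()` produce a complete miniature study —
candidate table, GTF, QTLdb-dialect GFF — with ground truth computed at
generation time by direct position comparison, independent of the indexed
join. Defaults describe a small but structurally realistic setting: a
3-chromosome genome of 10 Mb each, 150 genes with log-normal lengths
(mode ~20 kb), 500 QTL records with log-uniform spans from single base pairs
to multi-Mb blocks (mimicking QTLdb's heterogeneous record sizes), 25
candidate windows of 50 kb, and a 12-trait catalog over the six cattle QTL
classes with deliberately uneven abundances (milk traits over-represented,
as in the real database). All randomness flows through one seeded generator;
the same spec and seed reproduce files byte for byte, and the global RNG
stream is left untouched.

`planted_trait` raises one trait's record density inside the candidate
windows by `planted_fold` (default 10x), giving a known positive control.
The package's planted-signal validation plants the *most abundant* catalog
trait: a power analysis at design time showed that planting a rare trait
(K ≈ 25) leaves the planted count within reach of the discrete noise floor,
which tests the fixture's sample size rather than the method.

Two statistical validations run on this generator. Under a null
configuration — uniform trait assignment, uniform candidate placement, 600
records, 25 windows of 200 kb so that counts are large enough for the
discrete p-values to be near-continuous — pooled enrichment p-values over
200 seeds are approximately uniform (fraction below 0.05 within
[0.02, 0.09]). Under the planted configuration the planted trait must rank
first by p-value in at least 95 of 100 seeds. Problem sizes for these
studies were fixed at design time for the statistical reasons above.

What the generator does **not** emulate: linkage disequilibrium, real marker
density, chromosome-length heterogeneity, assembly-specific coordinates, or
correlated trait placement. Passing tests therefore demonstrate the
correctness of the joining, counting and testing machinery under the stated
model — not robustness to LD-induced clustering of real candidate markers,
which an analyst should address upstream (e.g. by pruning) as in any
enrichment analysis of this type.

## Degenerate inputs and tie-breaks

* Records with missing or inverted coordinates, missing identifiers or
  duplicated IDs are dropped at import with per-reason counts kept in the
  database's provenance — never imputed.
* A file with data lines but no usable records is a fatal error; a file with
  no data lines loads as a valid empty database (an empty simulation is
  representable).
* Candidates on chromosomes absent from the database yield an empty result
  with a warning (the common symptom of a naming-convention mismatch), not
  an error; candidate tables offering both marker and interval columns use
  the interval schema and say so.
* An annotated trait absent from the database in scope (`K = 0`) is fatal:
  it means the annotation and database are out of sync, and no p-value is
  meaningful.
* Output rows preserve candidate input order, order features by start
  position within a candidate, and break p-value ties alphabetically, so
  results are deterministic.

## Known limitations

* The QTL-class extraction rule (feature-type column first, `trait_type`
  attribute as fallback) covers the observed dialect variants but is
  configurable (`class_from`) because the dialect is not formally specified.
* Chromosome-wide scope treats chromosomes independently; there is no
  between-chromosome dependence model.
* The hypergeometric null assumes records are exchangeable draws; clustered
  records (fine-mapped variants deposited as many near-identical entries)
  violate this and inflate significance, which record-ID deduplication
  mitigates but cannot eliminate.
* Compositions and overlaps default to unique-record semantics; row
  semantics are available via `count = "rows"` where the alternative
  reading is defensible.
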