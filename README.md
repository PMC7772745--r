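# lociqtl

Gene and QTL annotation, cross-study comparison and enrichment testing for
candidate loci in livestock genomes.

Genome-wide association studies, RNA-seq contrasts, ROH and CNV scans all end
the same way: a table of candidate markers or intervals that needs biological
context. `lociqtl` joins such tables against two reference resources — gene
annotation in Ensembl-style GTF and previously reported QTLs in the GFF
dialect distributed by Animal QTLdb — and then quantifies what the annotation
means: which records are shared between studies or models, how the QTL
classes are composed, and whether any trait is over-represented beyond the
research-effort bias of the database.

## The statistical core

A trait's over-representation among annotated QTL records is tested with the
upper-tail hypergeometric model. Within a scope (one chromosome, or the whole
genome) let

* `k` — unique QTL records of the trait annotated within the candidate
  regions,
* `K` — records of that trait in the database,
* `n` — all unique annotated records,
* `N` — all database records.

The enrichment p-value is

```
p = P(X >= k),   X ~ Hypergeometric(N, K, n)
```

computed in log space from log-binomial coefficients with a log-sum-exp
reduction, so tails far beyond double underflow (the bundled cattle example
reaches 1.56e-171) are exact. Families of tests are corrected with
Benjamini–Hochberg FDR by default, over exactly the emitted tests. The
*richness factor* `k/K` (x-axis of the bubble plot) measures what fraction of
the database's records for a trait fall inside the candidate regions.

Annotated records are deduplicated by record ID before counting — several
markers hitting the same QTL record count it once — which is what keeps
`k <= K` and the model valid.

## Worked example

The package ships three micro-datasets (`toy_worked_examples()`). Annotating
3 candidate regions against a 12-gene GTF where each region contains 4 genes:

```r
library(lociqtl)
ex  <- toy_worked_examples()
db  <- import_gtf(ex$genes)
ann <- annotate_loci(read_candidates(ex$regions), db, window = 0)
nrow(ann)
#> [1] 12
annotation_summary(ann)$n_hits
#> [1] 4 4 4
```

Each output row pairs one candidate with one overlapping feature, carrying
the candidate's metadata columns through — 3 regions x 4 genes = 12 rows.

Group overlap is asymmetric by design. With group A holding 10 unique IDs,
group B holding 5, and 5 shared:

```r
g <- readr::read_csv(ex$groups, show_col_types = FALSE)
overlap_among_groups(g, "group", "id")
#> <overlap_matrices over 2 group(s)>
#>   A            B
#> A 10 (100.00%) 5 (50.00%)
#> B 5 (100.00%)  5 (100.00%)
```

A shares 50% of *its* records with B, while B shares 100% of its own — each
row is scaled by that row group's size.

Enrichment on the bundled cattle male-fertility count table:

```r
counts <- readr::read_tsv(ex$counts, show_col_types = FALSE)
e <- enrich_from_counts(counts)
head(tidy(e), 3)
#> # A tibble: 3 x 10
#>   qtl                   chrom n_hits  n_db total_hits total_db    pvalue ...
#> 1 Scrotal circumference 5        132   134        347     5942 1.56e-171
#> 2 Scrotal circumference 18        11    13         41     2147 2.20e- 18
#> 3 Scrotal circumference 9         11    14         30     1395 2.04e- 17
plot_enrichment(e, top = 5)   # bubble plot: richness factor vs trait
```

The full pipeline — simulate a dataset, annotate, compare, enrich — is also
available from the shell via the installed `exec/lociqtl` script
(`annotate`, `compare`, `enrich`, `summarize`, `relate`, `simulate`
subcommands); every output file starts with a provenance header recording
the tool version, the command line and input checksums.

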