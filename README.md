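# rlkfam

Genome-wide identification and characterization of leucine-rich-repeat
receptor-like kinase (LRR-RLK) gene families, as a reusable, tested R
pipeline.

LRR-RLKs are plant plasma-membrane receptors — an extracellular stack of
leucine-rich repeats, one transmembrane helix, a cytoplasmic kinase
domain — and one of the largest gene families in plant genomes (543
members in cultivated tetraploid cotton, 234 in Arabidopsis). Surveys of
the family share a standard recipe, which this package implements end to
end for anyone running or auditing such a survey:

- **Screening** — an internal word-seeded Smith–Waterman search (BLOSUM62,
  affine gaps 11/1, Karlin–Altschul E-values with λ = 0.267, K = 0.041),
  plus parsers for precomputed BLAST outfmt-6, HMMER domtblout, TM/SP call
  tables; candidates at E ≤ 1e-10.
- **Membership rule** — a protein is a family member iff it has ≥ 1 LRR
  domain hit, ≥ 1 kinase hit and ≥ 1 TM segment; failed criteria are
  reported per protein.
- **Phylogeny** — progressive profile–profile alignment, p-distances
  (complete or pairwise gap deletion), classic neighbor joining
  (Q(i,j) = (n−2)d(i,j) − Σ_k d(i,k) − Σ_k d(j,k)), seeded bootstrap
  supports, and reference-anchored subclade assignment by
  smallest-enclosing-cluster majority vote.
- **Genome mapping** — chromosomal distribution with A/D-subgenome
  classing, and tandem-duplication-event calling: two family genes link
  when ≤ 1 gene of any type intervenes, or exactly 2 intervene within
  1 Mb; events are connected components of the link graph.
- **Characterization** — average molecular weight, Bjellqvist-pKa
  isoelectric point, the 24-residue LRR consensus scan
  (`L--L--L--L-L--N-L--G-IP-`), Kyte–Doolittle TM fallback, domain
  architecture strings and census-style subclade summaries.
- **Expression & physiology** — RPKM (1e9·c/(N·L)), log2(x+1) + row
  z-score normalization, 1−Pearson average-linkage heatmap clustering,
  qPCR ΔΔCt fold changes (2^−ΔΔCt), Student/Welch t-tests with `*`/`**`
  stars, chlorophyll-from-absorbance equations and electrolyte leakage
  (100·EL1/EL2).
- **Synthetic data** — a seeded generator of complete toy inputs (FASTA,
  GFF3, evidence tables, counts, qPCR, physiology) with planted ground
  truth, so every stage is testable offline.

Everything is data-frame-first: functions take tibbles and return
tibbles, results chain with the pipe, `tidy()`/`glance()` summarize the
report object, and `plot_*()` helpers return ggplots.

## Worked example

```r
library(rlkfam)

ds <- generate_dataset(sim_config(), seed = 7, dir = tempdir())
rec <- end_to_end_recovery(ds)
rec$membership_precision   # 1
rec$membership_recall      # 1
rec$subclade_accuracy      # 1
rec$tde_exact_match        # TRUE

cfg <- pipeline_config(
  proteome = ds$paths[["proteome"]], gff = ds$paths[["gff"]],
  references = ds$paths[["references"]], ref_labels = ds$paths[["ref_labels"]],
  domains = ds$paths[["domains"]], tm_calls = ds$paths[["tm"]],
  counts = ds$paths[["counts"]], gene_lengths = ds$paths[["gene_lengths"]])
report <- run_pipeline(cfg, quiet = TRUE)
report
#> LRR-RLK family analysis report
#>   members:         20 of 26 candidates
#>   subclades:       4
#>   TDE events:      3 involving 6 genes
report$census
#> # A tibble: 4 × 3
#>   subclade     n percent
#>   <chr>    <int>   <dbl>
#> 1 I            5      25
#> 2 III          5      25
#> 3 XI           5      25
#> 4 XII          5      25
```

At zero evidence noise the pipeline recovers the planted family exactly
(precision = recall = 1), assigns every member to its planted subclade,
and calls exactly the planted tandem-duplication events — the 26
candidates above are the 20 planted members plus 6 decoys, each of which
violates exactly one membership criterion and is rejected with the
violated criterion named in the report.

The census machinery also reproduces the published family-survey
arithmetic from the shipped count tables:

```r
subclade_census(family_census("cotton"))   # totals 543; subclade XII -> 23.6%
subclade_census(family_census("arabidopsis")) # totals 234; subclade I -> 18.8%
```

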