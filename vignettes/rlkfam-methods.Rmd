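---
title: "Methods: genome-wide LRR-RLK family analysis with rlkfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide LRR-RLK family analysis with rlkfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlkfam)
```

## The problem

Leucine-rich-repeat receptor-like kinases (LRR-RLKs) are plasma-membrane
receptors built from an extracellular stack of LRR repeats, a single
transmembrane (TM) helix and a cytoplasmic kinase domain; they form one of
the largest receptor families in plants and are repeatedly the locus of
stress-signalling discoveries (the salt-stress SIF subfamily among them).
Genome-wide surveys of the family follow a conserved recipe: screen a
proteome by similarity against a reference family, filter candidates by
domain evidence, classify the survivors into subclades against labeled
reference proteins in a phylogeny, and characterize the resulting members
(chromosomal distribution, tandem duplication, gene structure,
physicochemical properties, expression, and—when a member is functionally
tested—stress physiology).

`rlkfam` implements that recipe as a tested pipeline whose every stage can
be exercised on synthetic genomes with planted ground truth, so that the
behaviour of each rule is verifiable without any external download.

## Candidate screening

The screen is a word-seeded Smith–Waterman search: a query/subject pair is
aligned only when the two sequences share at least one exact 3-mer, and
gated pairs receive a *full* optimal local alignment (BLOSUM62; a gap of
length $g$ costs $11 + g$). Consequently the reported score never exceeds
the unseeded Smith–Waterman optimum, and equals it whenever an exact seed
of length $\ge 3$ exists—a property the tests check against an independent
implementation. E-values use the Karlin–Altschul formula
$E = K m n e^{-\lambda S}$ with the standard gapped BLOSUM62 constants
$\lambda = 0.267$, $K = 0.041$; edge-effect correction is omitted because
the search operates at desk scale. These constants are a package decision,
not a fitted quantity. Candidates are subjects hit at
$E \le 10^{-10}$, deduplicated; the direction flag covers searches run the
other way around.

Membership then requires three pieces of evidence simultaneously: at least
one LRR-category domain hit, at least one kinase-category hit, and at
least one TM segment. The rule is applied verbatim and each failed
criterion is recorded per protein in a `reasons` column, so sequences that
narrowly miss (a real survey counted one kinase-less outlier among its
members) surface in the output instead of being silently special-cased.
Domain names map to categories through a replaceable table
(`default_domain_categories()`): upstream web tools do not standardize
which HMM profiles count as "kinase domain", so the mapping is data, not
code.

## Phylogeny and subclade assignment

The alignment is progressive: fractional shared 3-mers give pairwise
distances, UPGMA (average linkage) gives the guide tree, and profiles are
merged by profile–profile Needleman–Wunsch under BLOSUM62 expected column
scores with affine gaps (open 10, extend 0.5). A precomputed aligned FASTA
can bypass this stage (`read_alignment()`).

Distances are p-distances (proportion of differing residues among compared
positions). Two gap treatments are implemented because the two are both
defensible readings of common practice: `complete_deletion` (drop every
column containing a gap or `X` anywhere; the default) and
`pairwise_deletion` (drop positions per pair). Neither is asserted as the
"true" setting of any published analysis.

Trees come from classic neighbor joining:
$Q(i,j) = (n-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$, join the argmin,
branch lengths by the two-point formula. Ties in $Q$ break by the
lexicographically smallest node-index pair—reproducibility is preferred
over fidelity to any particular desktop program's internal order. Negative
branch lengths are clamped to zero with the deficit moved to the sister
edge, preserving path lengths through the join. On additive matrices the
implementation reconstructs the generating tree exactly (topology and
lengths to 1e-9), which the tests verify on random trees and against the
independent `ape::nj`.

Bootstrap supports resample alignment columns with replacement (seeded
RNG, default 1000 replicates; the acceptance runs scale this to 100 for
size, not correctness); the support of an internal edge is the percentage
of replicate trees containing the same bipartition. Under complete
deletion the resampling pool is the post-deletion column set.

Subclade assignment formalizes "grouped with a labeled reference": for
each query leaf the smallest bipartition side containing the query and at
least one reference votes by majority reference label, ties broken by the
patristically nearest reference. A query whose smallest
reference-containing cluster spans more than half of all leaves is
declared `unassigned`—that is this package's operationalization of a
phylogenetic outlier that attaches outside every reference cluster, and
the threshold (0.5) is exposed as `max_cluster_frac`. The published
surveys never state a computable criterion for "grouped with"; this rule
is ours and is documented as such.

## Chromosomal distribution and tandem duplication

Genes are ranked 0-based by start coordinate within each
chromosome/scaffold over the *complete* annotation—family and non-family
genes alike—because the duplication rule counts interruptions in gene
units. "Adjacent" is read as: two family genes are linked when at most one
gene of any annotated type lies between them, or when exactly two
intervene and the end-to-start genomic gap is within 1 Mb. Events are
connected components of this link graph, merged transitively (a chain of
pairwise-linked genes is one event, which is how a survey can report fewer
events than genes involved). The implementation scans consecutive family
genes in rank order; the tests prove it equivalent to the brute-force
all-pairs + union-find definition on 200 random toy genomes, and invariant
under chromosome reversal.

Exon–intron arithmetic is 1-based inclusive end to end (GFF3 native);
`length = end - start + 1`, intron $k$ is the gap between exons $k$ and
$k+1$. No coordinate system conversion happens anywhere in the package.

## Protein characterization

Molecular weight is the sum of average-isotopic residue masses plus one
water (matching the default of the common web calculators); `X` uses the
mean residue mass. The isoelectric point bisects the
Henderson–Hasselbalch net charge to 0.001 pH with the Bjellqvist-style
pKa set (`pka_bjellqvist()`, swappable), the set used by the widespread
pI/MW servers. The tests pin the bisection to a dense (1e-4 pH) grid
oracle within 0.01 pH.

The LRR consensus scan slides a 24-residue window matching
`L--L--L--L-L--N-L--G-IP-`: positions 1, 4, 7, 10, 12, 17 are Leu/Ile,
position 15 Asn, 20 Gly, 22 Val/Ile, 23 Pro; overlapping matches are all
reported. Table-style "number of LRRs" is reported both as LRR-category
domain hits (`n_lrr_domains`) and consensus-scan matches
(`n_lrr_consensus`) because published tables rarely state which counter
they used.

When no dedicated TM-call table is available, `hydropathy_tm_scan()` is a
stand-in predictor: Kyte–Doolittle window means (window 19, cutoff 1.6)
with maximal above-cutoff runs merged into segments.

## Expression and physiology analytics

RPKM is $10^9 c / (N L)$ with $L$ the summed exon length; when per-sample
mapped-read totals are unavailable the column sums of the count matrix
stand in for $N$. "Self-normalized log converted" values are
$\log_2(x+1)$ followed by a per-gene z-score (constant rows map to zeros);
the pseudocount and the row-z reading are package decisions where
heatmap-viewer conventions are ambiguous, and they are recorded here
rather than asserted as fidelity to any one tool. Clustering is
average-linkage over $1 -$ Pearson correlation.

qPCR quantification is ddCt: $\Delta C_t$ per replicate against the
in-sample reference gene, $\Delta\Delta C_t$ against the calibrator-group
mean, fold $= 2^{-\Delta\Delta C_t}$, with replicate-level folds retained
so group tests run on real replication. Group comparisons are two-sided
Student's t by default (Welch by flag), starred at p < 0.05 (`*`) and
p < 0.01 (`**`).

Chlorophyll content follows the printed absorbance equations, including
the widely circulated total-chlorophyll form
$(8.02 A_{663} - 20.20 A_{645})\,V/W/1000$ whose minus sign contradicts
the sum of the a and b equations; the internally consistent plus form is
available as `mode = "arnon_corrected"`, and the default reproduces the
printed form verbatim because the package does not presume to know the
original intent. Electrolyte leakage is $100 \cdot EL_1 / EL_2$.

## The synthetic-data generator

`generate_dataset()` emulates the inputs of a genome-wide survey with
full ground truth. Members are assembled from blocks: a 22-aa hydrophobic
signal peptide, an optional 120-aa malectin-like block (subclade I, as in
real families), $k$ instantiated copies of the 24-aa LRR consensus, a
19-aa hydrophobic TM stretch and a 260-aa kinase block. Subclade ancestors
diverge 0.35 substitutions/site from a common kinase seed; members diverge
0.10/site from their ancestor—the condition under which the package's
recovery guarantee (assignment accuracy $\ge$ 0.95 over 20 seeds) is
stated. Decoys omit exactly one block each, violating exactly one
membership criterion. The toy genome (A/D chromosomes plus an unanchored
scaffold, exercising the subgenome regex) plants five duplication
layouts: adjacent pair, one-gene interruption, two-gene interruption
within 1 Mb (all three are true events), two-gene interruption beyond
1 Mb and three-gene interruption (both negative). Counts are negative
binomial (size 5) with an 8-fold fiber-sample mean for the planted
fiber-high subclades across the ten standard fiber-development samples;
the qPCR table plants a 4-fold treatment effect; the physiology table
plants +30% chlorophyll and −40% electrolyte leakage in the silenced
group with 10% multiplicative noise and five biological replicates
(pigment-level noise scales both absorbances of a sample jointly, as
biological variation in extract concentration does; independent
per-absorbance noise would make the near-cancelling printed total
formula uninformative). These
defaults were chosen once as field-plausible study conditions and are not
tuned against test outcomes.

One global seed fans out to fixed per-component sub-seeds, so adding a
pipeline component never perturbs the draws of earlier ones, and the same
seed yields byte-identical output files.

What the generator does *not* emulate—and hence what green tests do not
establish about real data: realistic residue composition and
insertion/deletion structure (blocks mutate by substitution only),
alignment difficulty from length heterogeneity, annotation errors,
multi-isoform genes, mapping-induced count biases, and reference label
noise. Recovery guarantees on synthetic data bound the algorithmic
behaviour of the rules, not the biological error rate of a real survey.

## Problem sizes and numerical choices

The default synthetic study uses 4 subclades × 5 members + 2 references
each, 6 decoys and ~90 annotated genes; the test suite and the acceptance
script run the full pipeline at this size (20 seeded replicates for the
accuracy property) and scale bootstrap replicates to 60–100. Tolerances:
pI bisection 0.001 pH (tested to 0.01 against the grid oracle), NJ
additive reconstruction 1e-9, percentage rounding half-up to 1 decimal
(the printed-table convention; base R's banker's rounding would print
23.5 where published tables print 23.6). Degenerate inputs fail fast:
empty sequences, non-positive weights/volumes, EL1 > EL2, zero usable
alignment columns, non-symmetric distance matrices and mixed rank systems
are all errors, not warnings.

## Worked example

```{r example, eval = FALSE}
ds <- generate_dataset(sim_config(), seed = 7, dir = tempfile())
rec <- end_to_end_recovery(ds)
rec$membership_precision  # 1 at zero noise
rec$membership_recall     # 1 at zero noise
rec$tde_exact_match       # TRUE

cfg <- pipeline_config(
  proteome = ds$paths[["proteome"]], gff = ds$paths[["gff"]],
  references = ds$paths[["references"]], ref_labels = ds$paths[["ref_labels"]],
  domains = ds$paths[["domains"]], tm_calls = ds$paths[["tm"]],
  counts = ds$paths[["counts"]], gene_lengths = ds$paths[["gene_lengths"]])
report <- run_pipeline(cfg)
report$census
glance(report)
```

## Known limitations

The progressive aligner is a classic sum-of-pairs profile merger without
iterative refinement; on deeply diverged families with indel-rich
extracellular regions a dedicated aligner will outperform it, which is why
`read_alignment()` accepts external alignments. The E-value model omits
composition-based statistics and low-complexity masking. The subclade
rule depends on reference coverage: a subclade with no reference in the
tree is unrecoverable by construction. The TDE rule counts annotated
genes of any type as interruptions; surveys that count only
protein-coding genes will differ on annotations with many non-coding
features.
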