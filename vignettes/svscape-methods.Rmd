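---
title: "svscape: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{svscape: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery: what
each stage computes, which assumptions it makes, why the defaults are what
they are, and where a design was genuinely open and a choice had to be made.
It states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. The analysis in one paragraph

Two populations (think: a high-altitude bovid and taurine cattle) are
genotyped for structural variants from per-individual call sets. The call
sets are merged into one multi-sample site list, unreliable sites are
filtered out, per-site F~ST~ is computed, and the top 0.5 % of defined values
becomes the *high-F~ST~* candidate set. Each candidate is placed in a genomic
region category against gene models, yielding gene lists (any non-intergenic
hit; exonic/promoter hits). Bulk RNA-seq between the two groups yields
differentially expressed genes (DEGs). Single-cell matrices from the focal
tissue of both species are clustered per species, marker genes are called,
clusters are matched across species by profile correlation (with a novelty
rule for clusters that match nothing), and both species are co-clustered over
orthologs. Finally, the SV-derived, DEG and intersection gene lists are
tested for enrichment among each cluster's markers.

## 2. SV merging and filtering

**Merge rule.** Calls on the same chromosome and of the same SV type are
chained greedily in `(chrom, start)` order: a call joins the open chain if
its start — and, for non-insertions, its end — lies within `max_dist_bp`
(default 50 bp) of the *chain seed* (the first call of the chain). The
representative breakpoints are per-coordinate medians of the members;
`support` counts distinct contributing samples. Seed-anchored chaining was
chosen over centroid or complete-linkage clustering because it is
deterministic, order-stable under the coordinate sort, and directly
assertable (every member lies within the radius of its seed — a property the
test suite checks on stored members). The upstream tool this emulates also
accepts strand-agreement and length-ratio constraints; neither is stated in
the workflow we follow, so both are omitted.

**Genotype expansion.** The original workflow re-genotyped every sample at
merged breakpoints from alignments. Without reads, a sample that contributed
no call receives `hom_ref` by default (configurable to `missing`); a sample
whose call carried `./.` stays missing under either policy. This mirrors
"genotype everyone at every merged site" at desk scale and is the one place
where the absence of raw data forces a modelling substitute.

**Site filters.** `filter_callset` reproduces the documented semantics of
the standard flags: call rate ≥ `max_missing` (the flag names a minimum
call-rate, 0.5), minor allele count ≥ `mac` (3) over called genotypes, and
site QUAL ≥ `min_qual` (30).

## 3. Per-SV F~ST~

The default estimator is the Weir & Cockerham (1984) per-site
$\hat\theta = a/(a+b+c)$ with $r = 2$ populations, computed from genotype
counts — allele frequencies *and* observed heterozygote frequencies — so
departures from Hardy–Weinberg inside populations are handled correctly.
Estimates may be slightly negative and are reported unclamped, matching
common tooling. A site is undefined (`NA`) when a population has no called
genotypes or the denominator is zero (monomorphic overall). Bhatia's
formulation of Hudson's estimator is available as an option
(`estimator = "hudson"`).

Two numerical notes. First, with a single diploid per population the
finite-sample correction terms are 0/0; they vanish exactly when their
numerators do (as for a fixed difference, where the estimate is 1 at *any*
sample sizes ≥ 1), and the site is reported undefined otherwise. Second, the
balanced fixed-difference case is bitwise exactly 1; unbalanced cohorts are
exact up to floating-point associativity (≈ 1e-15), which the tests
acknowledge with a 1e-12 tolerance.

**Top-fraction selection.** `k = ceiling(fraction × n_defined)` with
`fraction = 0.005`; every site tied with the k-th value is included. The
inclusive tie rule is a deliberate choice: with many sites at F~ST~ = 1 any
exclusive rule would select an arbitrary subset, destroying reproducibility.
Undefined estimates count in neither numerator nor denominator.

## 4. Region classification

Seven mutually exclusive categories are assigned by fixed priority
`exonic(CDS) > UTR > intronic > promoter > upstream > downstream >
intergenic`, following variant-effect severity convention (the source
workflow used an external annotator whose collapsing rule is not printed).
Windows are strand-aware: promoter `[TSS − 2000, TSS − 151]`, upstream
`[TSS − 150, TSS − 1]`, downstream `[3' end + 1, 3' end + 150]`, mirrored on
the minus strand. The promoter is truncated where the 150 bp flank begins so
that "promoter" and "flank" stay disjoint classes — the workflow we follow
reports them as separate, non-nested counts. The true promoter definition
there (possibly peak-derived) is unrecoverable; this distance-based stand-in
is documented, not asserted as equivalent. Insertions are evaluated at their
insertion point; all other types as their full span, with any-overlap
semantics. Deletions additionally get a coding effect: total CDS overlap
length positive and not divisible by 3 is a frameshift, divisible by 3
in-frame.

## 5. Bulk differential expression

The published procedure pairs a normalisation step from a standard DE
package with a printed per-transcript decision rule. The printed rule — not
the package internals — defines the gene lists, so this module implements
exactly that rule and wraps no external DE machinery: median-of-ratios size
factors (geometric-mean-1 rescale; the median is taken in ratio space, as
the formula states), `x = log2(normalised + 1)`, per-gene two-sided Welch
t-test, screen `p < 0.05` and `|log2FC| ≥ 1` with the fold-change boundary
inclusive. log2FC is the difference of mean log2 values so the two screens
operate on the same scale. No multiple-testing correction enters the call —
the screen is on raw *p* — but a BH-adjusted column is emitted for
transparency. Genes with zero variance in both groups get `p = 1` when means
are equal and `p = 0` when they differ exactly (a noiseless difference is
evidence, not an artefact). One subtlety the tests document: the
geometric-mean-1 rescale means multiplying one sample by a constant rescales
*all* normalised counts by a common factor, which the `+1` pseudocount makes
faintly visible in log2FC; the *calls* are unaffected in practice and the
suite pins that down.

## 6. Single-cell pipeline

Per species: QC removes cells with fewer than `min_genes` detected genes
(strict `<`, species-specific: 300 for one input, 500 for the other, as
printed) or mitochondrial fraction above 0.20 (strict `>`); log-normalise
(`ln(1 + 10^4·count/total)`); scale genes to unit variance with values
clipped at ±10; PCA to 20 components; shared-nearest-neighbour graph
(k = 20, Jaccard weights over neighbour sets including self, edges pruned
below 1/15); Louvain at resolution 0.5 under a fixed seed. These defaults
mirror the toolkit ecosystem the printed parameters come from; all are
arguments. No highly-variable-gene selection is performed (none is stated in
the source workflow).

**Markers.** One cluster vs all other cells, per-gene Wilcoxon rank-sum
(two-sided, normal approximation with tie and continuity corrections —
verified against `wilcox.test` in the tests), BH across genes within a
cluster, `avg_log_fc` the difference of mean log-normalised expression
(natural-log scale, recorded in the table's `log_base` attribute). Retained:
`p_adj < 0.05`, `avg_log_fc > 1` and detection ≥ 10 % in-cluster. The
`> 1` filter is one-sided — positive markers only — reading the printed
threshold literally.

**Cross-species matching.** Per-cluster mean log-normalised profiles,
restricted to ortholog pairs, Pearson-correlated for every cluster pair. A
cluster is *novel* when its best correlation with the other species falls
strictly below `r = 0.31`; equality keeps the cluster, matching the strict
inequality as printed.

**Joint clustering.** Both matrices are restricted to orthologs and renamed
to a common namespace, log-normalised per species, concatenated, scaled
*jointly*, then PCA (30 PCs) and Louvain at resolution 0.1. The original
design called for per-species scaling before concatenation; implementation
showed that per-species z-scores manufacture a batch-like offset whenever
one species carries a cluster the other lacks (its presence shifts that
species' per-gene means and variances), and the joint step then split every
cluster cleanly by species — contradicting the intended behaviour that
shared cell types co-cluster across species. Joint scaling removes the
artefact for batch-free synthetic data. Either way this stage is a
simplified stand-in for anchor-based integration, adequate only because the
generator introduces no batch effects; on real cross-platform data an
anchor- or harmony-style correction would be required.

## 7. Integration statistics

The DEG-vs-SV-gene association is a Pearson chi-square on the 2×2 table over
the gene universe, df = 1, Yates correction off by default (large-count
regime; a flag is provided). The universe defaults to ortholog-mapped genes
— the expression comparison is only meaningful for genes present in both
species — and is configurable, since whether the original universes were
per-species expressed genes or all annotated genes is not stated.

Per-cluster enrichment: for marker set $M_c$ and list $L$,
`ratio = |M_c ∩ L| / |M_c|`; two-sided Fisher's exact test on
$[[|M_c∩L|, |M_c\setminus L|], [|L\setminus M_c|, |U\setminus(M_c∪L)|]]$;
and a *normalised ratio*, the z-score of the ratio across clusters within
each list. The source says only that proportions were "calculated and
normalized"; the within-list z-score is the simplest normalisation that
makes clusters comparable across lists of very different sizes, and raw
ratios are always emitted so any alternative can be applied downstream.

The one-vs-rest test converts list membership into 0/1 indicators over the
cluster's markers vs the pooled markers of all other clusters and applies a
two-sided Welch t-test (the published "T-test; two-tailed" on per-cluster
proportions is not derivable more precisely from its printed degrees of
freedom); the equivalent two-proportion z-test is reported alongside as a
cross-check.

## 8. The synthetic world

The generator's defaults state one concrete scenario and stay fixed:

| parameter | default | what it states |
|---|---|---|
| cohort | 3 + 26 diploids | the two sequenced populations |
| SV sites | 10,000; 50 divergent at `delta = 1` | genome-wide SVs with a small fixed-difference tail |
| background frequencies | Beta(0.8, 0.8), shared across populations | U-shaped site-frequency spectrum without extra machinery |
| genotypes | Hardy–Weinberg draws; 2 % missing at background sites; divergent sites fully called, high QUAL | fixed differences are the confidently genotyped tail |
| site quality | N(60, 10), 2 % of background sites N(20, 3) | gives the QUAL ≥ 30 filter real work |
| breakpoint jitter | start ±20 bp, length ±5 bp per sample | caller noise strictly inside the 50 bp merge radius |
| placement | category drawn first (intergenic 0.55, intronic 0.20, promoter 0.06, upstream/downstream 0.05 each, exonic 0.05, UTR 0.04), locus second, starts ≥ 150 bp apart | every category attainable; merge cannot chain distinct SVs |
| bulk | 5 + 5 samples, gamma-Poisson, dispersion 0.1, 200 DE genes at |log2FC| = 2 | the paired-lung comparison |
| single cell | 5 shared clusters × 150 cells/species, 10 markers each (×e²), one extra cluster with its own program in one species; depth LN(log 8000, 0.2); 10 `MT-` genes at 5 % of counts; 3 % failing cells (25–60 % mito), 2 % low-depth cells | two comparable atlases with one genuinely novel population and QC casualties |
| orthologs | 90 % of genes, same-id pairs | near-complete homology with a species-specific remainder |

Design notes on the generator worth making explicit:

* **Divergent sites are fully called.** Missingness at a fixed difference
  would entangle two unrelated failure modes (call-rate filtering and
  frequency estimation) in the recovery guarantee; real fixed differences
  are also the easiest sites to genotype. The 100 %-recovery acceptance
  criterion is a statement about the pipeline, not about luck in the
  missingness draw.
* **The novel cluster has its own expression program**, not merely extra
  markers. A marker-tweak cluster would still correlate ≈ 1 with everything
  through the shared baseline and could never fall below the 0.31 novelty
  threshold; a distinct program is what "a new cell population" means in
  this framework. Consequence: marker *recall* is asserted for all seeded
  sets, but marker *precision* only for shared clusters — the novel
  cluster's entire program is legitimately differential.
* **Shared world, species-specific cells.** The baseline program, marker
  assignments and the novel program are drawn under a species-independent
  RNG stream; per-species streams add only cells and noise. Both species
  therefore agree on what the clusters *are* while sharing no cells.
* **What a green test does not establish.** The generator has no doublets,
  no ambient RNA, no batch or library-composition effects, no linkage
  between SVs, no overlapping genes or alternative isoforms, and Poisson
  (not overdispersed) single-cell noise. Green tests certify the
  *statistical contracts* of each stage on data satisfying their
  assumptions, not robustness to any of the above.

## 9. Determinism and numerics

Every stochastic operation takes a seed and runs under `withr::with_seed`,
so library calls never consume global RNG state; two runs of
`run_pipeline()` with one seed are file-for-file identical (the run report
deliberately excludes wall-clock timing). Medians of even-length member sets
are floored to stay on integer coordinates. Scaling clips z-scores at ±10.
Wilcoxon p-values use the normal approximation (exact enumeration is
infeasible at hundreds of cells and matches to ~1e-10 where checked).
Fisher's two-sided p is the sum of hypergeometric point probabilities ≤ the
observed one — the acceptance suite verifies this exhaustively for all
tables with N ≤ 26 and by dense sampling up to N = 60, the literal full
enumeration being several minutes of `fisher.test` calls.

## 10. Known limitations

* No breakpoint refinement, multi-allelic SVs, or re-genotyping from reads;
  translocations are excluded at parse time (their length is ill-defined in
  the upstream caller's output).
* One transcript per gene; no isoform-aware consequence prediction beyond
  frameshift/in-frame.
* The F~ST~ stage supports exactly two populations and no windowed or
  significance-tested variants.
* Cross-species integration assumes batch-free data (see §6); cluster
  *identities* (endothelial, immune, …) are user-supplied labels, never
  inferred.
* The bulk DE stage has no dispersion shrinkage or covariates; it
  implements a printed screening rule, not a full GLM framework.
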