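---
title: "Differential methylation from methyl-capture tags: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential methylation from methyl-capture tags: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrcap)
```

## What the workflow does

`dmrcap` implements an integrative analysis of methyl-capture sequencing for
small group-structured cohorts (the canonical design is 5 controls vs 4
cases). Methyl-CpG-binding-domain capture enriches methylated DNA fragments,
so sequencing coverage is a proxy for methylation density. The workflow has
five statistical stages:

1. **Region discovery.** For every *ordered* pair of samples, tags (5′
   position + strand) are shifted 75 bp toward the presumed fragment centre
   and a 150 bp window slides along the genome in 10 bp steps. A window is a
   candidate when the upper-tail Poisson probability of the treatment count
   is below 10⁻⁵ under λ = max(genome-wide control rate, local control rate
   in 10 kb) × window width × library-size ratio. Candidates from all pairs
   are merged (book-ended intervals fuse, as `bedtools merge` does).
2. **Differential testing.** Tags are counted per merged region
   (half-open assignment of shifted positions), regions whose count sum falls
   below the 50th centile are dropped (30th for gene-level expression
   counts), per-sample TMM factors correct composition bias, dispersions are
   estimated by conditional NB likelihood with weighted-likelihood shrinkage,
   and a two-group exact NB test with BH adjustment yields the DMR table.
3. **Feature enrichment.** Significant regions (p < 0.01), split into
   hyper- and hypomethylated, are classified against CpG islands, gene
   bodies, exons, introns, strand-aware 3 kb promoters, 1 bp TSSs and the
   non-genic complement (overlap ≥ 1 bp). Each feature's 2×2 table gets a
   conditional-maximum-likelihood log2 odds ratio with an exact conditional
   95% CI and a two-sided Fisher exact p.
4. **Coupling to expression.** Genes are ranked by −log10(p) × sign(logFC)
   from the expression test; interval-derived gene sets (per genic feature ×
   methylation direction) are scored by preranked GSEA with gene-set
   permutations.
5. **Validation statistics.** Bisulfite clone matrices (per-clone
   Mann–Whitney, exact for small samples; per-CpG Fisher) and qPCR ΔΔCt
   relative quantification with two reference genes, plus t/ANOVA-Bonferroni
   group comparisons.

## Models and numerical choices

**Window caller.** This is a deliberate simplification of a
model-building peak caller: the shift is fixed at 75 bp (half the typical
200–300 bp capture fragment) rather than estimated, and the local background
uses a single 10 kb scale instead of a multi-scale ensemble. At toy-genome
scale the extra scales change nothing measurable; the fixed shift matches
the intended use on 36 bp single-end tags. Both orderings of each sample
pair are compared so gains and losses are both discoverable; an enrichment
caller cannot see depletion below background directly (λ is floored at the
genome-wide rate), so losses surface as enrichment of the opposite member of
the pair.

**TMM.** The reference column is the one whose 0.75 quantile of scaled
counts is closest to the mean such quantile. Log-ratios are trimmed 30%
each side, absolute intensities 5%, and the factor is 2 to the
precision-weighted trimmed mean, with factors rescaled to multiply to one. A
sample whose library is inflated by a few high-abundance rows receives a
factor *below* one — its effective library grows to absorb the inflated
content. The implementation agrees with the reference implementation in
edgeR to ~10⁻⁶ on typical matrices (ties in the trim are broken
differently, worth ~0.1% in adversarial cases).

**Dispersion.** The common dispersion maximizes the conditional NB
log-likelihood of counts scaled to a common library, conditioned on
per-group sums, pooled over rows; the likelihood is evaluated on a 50-point
log-spaced grid in [10⁻⁴, 4] and refined by quadratic interpolation.
Tagwise values maximize the per-row likelihood plus `prior_df` (default 10)
residual-df-equivalents of the pooled curve; `prior_df = Inf` recovers the
common value exactly. The default of 10 is a design choice — the method the
workflow follows does not document its prior weight — and is exposed in
`pipeline_config()`.

**Exact test.** Counts are equalized to the *median* effective library
(robust: rescaling one sample's depth leaves the target, and hence the
p values, essentially unchanged; a geometric-mean target would shift with
the scaling). Conditional on a row's total pseudo-count, the case-group sum
follows a generalized hypergeometric law whose success probability cancels;
the two-sided p sums all outcomes with probability ≤ the observed one, the
same convention as Fisher's exact test. At dispersion zero this reduces to
an exact binomial split, which the tests verify by enumeration. For totals
above 20,000 the support is pruned to ±15 standard deviations (omitted mass
< 10⁻¹²). The logFC adds a proportional prior count of 0.125 per sample, so
zero counts never produce infinite fold changes.

**Odds ratios.** Table-style CIs in this workflow are asymmetric around the
estimate, which identifies a conditional-exact method: the point estimate
solves E[a | margins; ψ] = a(observed) under Fisher's noncentral
hypergeometric distribution, and the CI bounds solve the one-sided tail
equations at α/2 (Woolf's normal interval is available as an option). With
a zero cell the conditional MLE degenerates, so the point estimate falls
back to the Haldane–Anscombe corrected sample odds ratio.

**GSEA.** "Gene-set permutation" means size-matched random draws from the
ranked universe (the preranked tool's semantics), not sample permutation —
with 4 + 5 samples there are too few sample permutations to be useful. The
weight exponent defaults to 1; NES divides ES by the mean |null ES| of
matching sign; FDR q compares each NES with the pooled sign-matched null NES
distribution. Ranking ties break lexicographically by gene id so results
are reproducible.

**Clustering.** Rows are z-scored; Euclidean distance with complete
linkage (the default of the common heat-mapping tool) clusters rows and
columns; columns are ordered by label before clustering so the tree is
invariant to input order. Constant rows are dropped with a warning.

**Coordinates.** Everything inside the package is 0-based half-open (BED
convention); conversion to 1-based closed happens only at the
`GenomicRanges` boundary. "Overlap" always means ≥ 1 bp of intersection,
so book-ended intervals do not overlap but do fuse under merging.

## The synthetic study

The generator exists so every downstream stage is testable without
external data, and its defaults *are* the study conditions:

* **Toy genome** — a few chromosomes of 1–4 Mb carrying non-overlapping
  stranded genes (2–20 kb, 1–6 exons) and 300–1500 bp CpG islands, 70% of
  them inside gene bodies. With ≥ 2 chromosomes the last is flagged
  *spared* and receives no differential effects, emulating the X-chromosome
  sparing seen in capture studies.
* **Methylation landscape** — disjoint effect intervals (500–2000 bp),
  80% anchored on CGIs or gene bodies. Every effect is a methylated region
  enriched 4-fold over background in *both* groups — capture pulls down
  methylated DNA in every sample — and the differential fold (uniform 4–8)
  multiplies the gaining group: the case group for hypermethylation, the
  control group for hypomethylation. Effects are placed disjoint because
  overlapping hyper and hypo effects would cancel multiplicatively and blur
  the planted truth. Capture efficiency and fragment-size distribution are
  not modelled; the density model is an assumption of this artifact.
* **Tags** — per sample, a Poisson(depth) total; positions drawn from the
  group's piecewise-constant density; uniform strands; a configurable
  fraction of tags are exact copies of other tags (PCR duplicates) that
  deduplication must remove. Default depth 2 × 10⁵ tags per sample gives
  window-level background λ ≈ 7.5 on a 4 Mb genome — comfortably inside the
  caller's operating range.
* **Expression** — log-normal baseline means scaled to the depth,
  NB-distributed counts (dispersion 0.1); a gene whose body overlaps a
  hypermethylation effect is repressed by `coupling` (default 1) log2 units
  in the affected group, and activated for hypomethylation.
* **Validation assays** — Bernoulli bisulfite clone calls at configurable
  per-CpG proportions; qPCR Ct values where the target's noiseless Ct is
  the mean reference Ct minus log2 of the true relative expression, so ΔΔCt
  recovery is exact at zero noise.

What the generator does *not* emulate: biological within-group
variability of methylation (within a group, samples differ only by
sampling noise), sequence content, bisulfite conversion failure,
fragment-length effects, and correlated CpGs. Passing tests therefore
demonstrate the *statistical machinery* — calibration, recovery, coupling
detection — on data satisfying the model's assumptions, not performance on
real tissue.

## Problem sizes used in the checks

The simulation studies are sized to the cohort the workflow targets while
staying quick enough to run routinely: null calibration uses 2,000 null
regions (plus 100 planted at logFC +1) at 10⁶ counts per sample with 4 vs 5
samples; the coupling contract runs the full tag→DMR→GSEA path ten times on
a 4 Mb single-chromosome genome with 200 genes and 60 planted effects
(1,000 gene-set permutations); clustering recovery uses 400 null + 80
differential rows per run. With 4 vs 5 samples and dispersion 0.1 a single
region's logFC estimate has a standard error near 0.3, so recovery is
judged on the *mean* planted estimate (a bias criterion), not on per-region
absolute error, which no estimator could push below the sampling noise.

## Known limitations

* The exact test conditions on rounded pseudo-count sums; p values are
  stable under depth rescaling to ~1%, not to machine precision.
* The window caller reports fused significant windows, not summit-refined
  peaks; region boundaries are only as sharp as the 10 bp step.
* Group designs beyond two groups must be run as separate case-vs-control
  contrasts; there is no GLM path.
* The non-genic feature is the complement of gene bodies ∪ promoters; an
  alternative (complement of gene bodies only) is switchable in
  `feature_catalog()`.
* Fisher-noncentral CIs use the same tail convention as `fisher.test`;
  agreement with it is ~10⁻³ log2 units (different root-finding), well below
  the 3-decimal reporting precision.
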