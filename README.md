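# dmrcap

Differential DNA-methylation analysis for methyl-capture sequencing of
small group-structured cohorts, with a synthetic-data generator that makes
the whole workflow testable without external downloads.

Methyl-CpG-binding-domain capture enriches methylated DNA before
sequencing, so tag coverage is a proxy for methylation density. Given tag
alignments (chromosome, 5′ position, strand, sample) for two groups of
samples — the canonical design is 5 controls vs 4 cases — `dmrcap`
discovers differentially methylated regions (DMRs), quantifies where in the
genome they fall, and couples them to gene expression:

1. **Region discovery** — for every ordered sample pair, tags are shifted
   75 bp toward the fragment centre and a 150 bp sliding window is tested
   against λ = max(genome-wide, local 10 kb) control rate × library-size
   ratio; windows with Poisson upper-tail p < 10⁻⁵ are fused and candidates
   from all pairs merged (book-ended intervals fuse).
2. **Differential testing** — tags counted per region, regions below the
   50th centile of count sums dropped (30th for expression), TMM
   normalization, conditional-likelihood dispersion estimation with
   weighted-likelihood shrinkage (prior df 10), a two-group exact
   negative-binomial test, and Benjamini–Hochberg FDR.
3. **Feature enrichment** — hyper- vs hypomethylated regions (p < 0.01)
   classified against CpG islands, gene bodies, exons, introns, 3 kb
   strand-aware promoters, TSSs and non-genic space (overlap ≥ 1 bp);
   per-feature 2×2 tables summarized as conditional-maximum-likelihood
   log₂ odds ratios with exact 95% CIs and two-sided Fisher exact p.
4. **Expression coupling** — genes ranked by −log₁₀(p) × sign(logFC);
   interval-derived gene sets (genic feature × methylation direction)
   scored by preranked GSEA with 1000 gene-set permutations (ES, NES,
   nominal p, FDR q).
5. **Validation statistics** — bisulfite clone matrices (exact
   Mann–Whitney on per-clone methylation, per-CpG Fisher tests) and qPCR
   relative quantification by the comparative ΔΔCt method with two
   reference genes.

The synthetic module (`generate_toy_genome`, `random_landscape`,
`simulate_capture_tags`, `simulate_expression_counts`,
`simulate_bisulfite_clones`, `simulate_qpcr_plate`) plants known
hyper-/hypomethylation effects concentrated on CpG islands and gene bodies
(one chromosome spared), with expression inversely coupled to gene-body
methylation, so every stage can be checked against ground truth.

## Worked example

The numbered scripts under `analysis/` run the full study on synthetic
data (`Rscript analysis/01_simulate.R`, then `02`…`06`). Abridged output:

```
02: tags after dedup: 1668411
    ordered comparisons: 72 | raw candidates: 4001 | merged regions: 64
03: regions tested: 32 | DMRs p<0.01: 32 ( 14 hyper / 18 hypo )
    genes tested: 105 | DE p<0.01: 21
    column dendrogram top split: CTRL_1:1 ... CTRL_5:1 PILO_1:2 ... PILO_4:2
05: gene-body hypermethylation vs expression: ES -0.952 FDR 0.00323
       -> repression coupling reproduced
06: Mann-Whitney U: 572 two-sided p: 3.89e-09
    group   mean_rq     sd_rq   n
     CTRL  1.002227  0.075684  5
     PILO  0.246275  0.008888  4
```

Reading this: 72 ordered pairwise comparisons produced 64 merged candidate
regions, of which 32 survive the centile filter and all 32 test
differential at p < 0.01 (the planted folds are strong); hierarchical
clustering of their z-scored profiles splits the cohort exactly into
control and case; GSEA finds the genes whose bodies gained methylation
enriched among repressed genes (negative enrichment score at FDR ≪ 0.25);
and the simulated validation assays recover the planted bisulfite
difference and the planted 4-fold expression knockdown (mean RQ 0.246 vs
a true 0.25).

`analysis/04_feature_enrichment.R` also recomputes the enrichment
statistics from a published contingency table shipped in
`inst/extdata/study_feature_contingency.tsv`:

```
  feature log2_or ci_low ci_high       p printed_log2_or
      CGI   2.881  2.142   3.708 9.6e-22           2.881
Gene body   0.681  0.450   0.912 3.7e-09           0.681
Non-genic  -0.605 -0.836  -0.374 1.8e-07          -0.605
   Intron   0.597  0.366   0.828 2.3e-07           0.597
     Exon   0.553  0.289   0.818 2.5e-05           0.553
 Promoter   0.293 -0.173   0.766 2.1e-01           0.293
      TSS   0.413 -0.264   1.113 2.2e-01           0.413
```

## Layout

- `R/` — the package: simulation, I/O (BED / gene-table / TSV / GMT /
  YAML), region discovery, differential testing, feature enrichment, GSEA,
  validation statistics, pipeline orchestration (`run_pipeline`).
- `analysis/01…06` — narrative drivers writing tables under `results/`.
- `tests/testthat/` — unit, property and end-to-end suites with
  brute-force oracles (and edgeR / fgsea / fisher.test as independent
  cross-checks).
- `vignettes/methylcapture-workflow.Rmd` — models, assumptions, numerical
  choices and limitations.
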