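# pairedconcord

Concordance analysis of gene expression between **paired tumour biopsies**.

## The problem

Window-of-opportunity trials and routine peri-surgical practice compare a
diagnostic core-cut biopsy with a second sample taken later — after specimen
X-ray (tens of minutes) or at surgical excision (about two weeks). Before any
treatment effect can be claimed from such a comparison, two questions have to
be answered from untreated pairs:

1. **How reproducible is a gene's measurement across two cores of the same
   tumour?** Intra-tumour heterogeneity plus assay noise set a floor on
   detectable change, and genes with a narrow dynamic range (e.g. *MKI67*)
   reproduce far worse than genes with a wide one (e.g. *ERBB2*).
2. **Which genes shift systematically between the first and second sample?**
   Cold ischaemia and the wounding of the first biopsy induce early-response
   and stress genes (*FOS*, *FOSB*, *DUSP1*, *JUN*), and such artifacts are
   easily mistaken for treatment effects.

`pairedconcord` implements the full analysis pipeline for this design, plus a
simulator of paired cohorts with known ground truth so that every statistical
claim the pipeline makes can be validated end to end.

## What is inside

| Module | What it does |
|---|---|
| readers/writers | TSV (and GEO series-matrix style) expression matrices with detection flags, sample sheets, signatures, centroid tables |
| preprocess | `log2_transform`, detection-fraction sample QC (paired exclusion, strict `< 30%`), never-detected probe filter, quantile normalization, per-batch gene-mean centering |
| concordance | per-pair profile correlations, per-gene cross-pair correlation with dynamic range, Euclidean/average-linkage clustering, sibling-leaf pair adjacency |
| paired_diffexp | per-gene paired *t*, sign-flip permutation p (exhaustive `2^n` for small n), Benjamini–Hochberg FDR, geometric-mean ratio `2^mean(d)` with 95% CI, elapsed-time drift screen |
| signatures | weighted-average metagene scores `sum(w*x)/sum(|w|)`, Wilcoxon/paired-*t* change tests, bundled public gene sets |
| subtyping | nearest-centroid intrinsic subtype calls, LumA−LumB correlation margins, paired concordance and margin summaries |
| cross_study | Fisher r-to-z comparison `Z = (atanh(r1) − atanh(r2)) / sqrt(1/(n1−3) + 1/(n2−3))` of a gene's pair correlation between studies |
| synthetic_data | variance-components cohort generator (between-tumour σ_b, within-pair σ_w, subtype centroids, shifts, time drift, batches, logistic dropout) + truth-recovery metrics |
| cli_app | `pairedconcord {simulate,preprocess,concordance,diffexp,signatures,subtype,compare-correlations,run}` and an end-to-end pipeline driver with manifest |

The per-gene reproducibility model is a variance-components one: two biopsies
of the same tumour have expected correlation equal to the intraclass
correlation ICC = σ_b²/(σ_b² + σ_w²), which the simulator exposes and the
tests verify.

## Worked example

```r
library(pairedconcord)

cfg <- simulation_config(n_tumours = 23, n_genes = 500,
                         shift_genes = c(g0001 = 1, g0002 = -0.6),
                         seed = 20160401)
co <- generate_cohort(cfg)
pp <- preprocess_pipeline(co$matrix, co$sheet)
pp$matrix
#> ExpressionMatrix: 500 probes x 46 samples (98.8% detected)

range(profile_correlation(pp$matrix, co$sheet)$r_pearson)
#> 0.983 0.987            # whole-profile agreement between the paired cores

pair_adjacency_concordance(hierarchical_cluster(pp$matrix), co$sheet)
#> ClusterConcordance: 23/23 pairs adjacent (100.0%)

de  <- paired_diffexp(pp$matrix, co$sheet, n_perm = 2000, seed = 20160401)
select_de(de, fdr_max = 0.05, fc_min = 1.25)
#> [1] "g0001" "g0002"    # exactly the two genes the simulation shifted
de[de$probe_id %in% c("g0001", "g0002"),
   c("probe_id", "mean_log2_diff", "p_permutation", "q_fdr", "gm_ratio")]
#>   probe_id mean_log2_diff p_permutation    q_fdr gm_ratio
#> 1    g0001          0.836         5e-04 2.97e-08    1.785
#> 2    g0002         -0.625         5e-04 7.09e-05    0.648

calls <- classify_subtypes(pp$matrix, co$centroids)
paired_subtype_concordance(calls, co$sheet)
#> PairedSubtypeConcordance: 0/23 discordant (0.0%), asymmetry p = 1

fisher_r_to_z_compare(0.712, 23, 0.194, 56)   # a gene correlated in one
#> Fisher r-to-z: r1=0.712 (n=23) vs r2=0.194 (n=56): Z = 2.65, p = 0.0081
```

The numbers mean: paired cores agree at r ≈ 0.98–0.99 genome-wide; every
pair is adjacent in the dendrogram; the two injected shifts (1.79-fold up,
0.65-fold down, i.e. 1.54-fold down) are the only FDR/fold-change
discoveries; subtype calls are fully concordant at this noise level; and a
pair correlation of 0.712 at n = 23 differs significantly (Z = 2.65,
p = 0.008) from 0.194 at n = 56.

## Command line

```sh
inst/cli/pairedconcord simulate --seed 11 --out-dir sim/
inst/cli/pairedconcord preprocess --in sim/expr.tsv --detection sim/detection.tsv \
    --sheet sim/sheet.tsv --out expr.norm.tsv --report report.json
inst/cli/pairedconcord diffexp --in expr.norm.tsv --sheet sim/sheet.tsv \
    --n-perm 10000 --seed 20160401 --fdr 0.05 --fc 1.25 --out de.tsv
inst/cli/pairedconcord run --seed 11 --out-dir results/
```

See `vignettes/paired-biopsy-concordance.Rmd` for the statistical model,
parameter choices and known limitations.
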