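---
title: "Models and methods for paired-biopsy expression concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for paired-biopsy expression concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairedconcord)
```

# The design and the model

Two core-cut biopsies are taken from each tumour: a *first* sample (at
diagnosis, or immediately on excision) and a *second* one (at surgery two
weeks later, or after a 20–60-minute delay for specimen X-ray). No treatment
intervenes, so any systematic difference between timepoints is a sampling or
handling artifact, and any non-systematic disagreement measures
intra-tumour heterogeneity plus assay noise.

All analyses work on log2 expression. The generative model behind both the
statistics and the simulator is a variance-components one. For gene $g$ and
tumour $t$ of intrinsic subtype $s(t)$:

$$\mu_{gt} = c_{g,s(t)} + b_{gt}, \qquad b_{gt} \sim N(0, \sigma_{b,g}^2)$$

and biopsy $k \in \{1, 2\}$ measures

$$x_{gtk} = \mu_{gt} + \varepsilon_{gtk} + [k{=}2]\,(\delta_g + \beta_g m_t) + \mathrm{batch},
\qquad \varepsilon \sim N(0, \sigma_{w,g}^2),$$

where $c$ is the subtype centroid profile, $\delta_g$ a systematic
second-sample shift (stress/early-response genes), $\beta_g$ a per-minute
drift slope, and $m_t$ the elapsed minutes. Two consequences drive the whole
package:

* the expected correlation between paired measurements of one gene across
  tumours is the **intraclass correlation**
  $\mathrm{ICC}_g = \sigma_{b,g}^2 / (\sigma_{b,g}^2 + \sigma_{w,g}^2)$ —
  so genes with a narrow between-tumour dynamic range *necessarily*
  reproduce poorly even when the assay is fine;
* a systematic $\delta_g$ back-transforms to the geometric-mean ratio
  $2^{\bar d_g}$ of second over first, which is what a paired design can
  estimate free of between-tumour spread.

# Preprocessing

The default recipe is `log2(x + offset)` (skippable when data are already
log scale) → detection-fraction sample QC → never-detected probe filter →
quantile normalization → per-batch gene-mean centering. The upstream
protocol that inspired this recipe describes its exact normalization only in
an unavailable supplement, so the pipeline fixes a conventional, auditable
default and records every stage in the `PreprocessReport`; each stage can be
switched off independently.

Decisions worth knowing:

* **Detection calls.** Bead-array detection p-values are thresholded at a
  configurable `detection_alpha` (default 0.05, the platform convention);
  the threshold is deliberately not hard-coded because the original
  criterion is not public.
* **Sample QC is pair-wise.** A sample with a detected fraction strictly
  below 30% is excluded *together with its partner*: every downstream
  statistic is paired, and an unpaired survivor would be unusable. The
  inequality is strict, so exactly 30% survives.
* **Quantile normalization ties** are resolved by averaging the target
  values over the whole tied block, which keeps a constant-valued sample
  constant (at the mean of the target distribution) and makes the transform
  idempotent.
* **Batch centering** removes per-gene batch means and restores the global
  gene mean. It removes batch *main* effects only — no empirical-Bayes
  shrinkage (ComBat-style) is attempted, deliberately: with n in the tens
  and a paired design, main-effect centering is transparent and sufficient.
* Studies are normalized **separately per `study_id`** by default; they have
  different probe universes, and joint normalization would couple cohorts
  that were hybridized years apart.

# Concordance

Whole-profile agreement is the Pearson (and Spearman) correlation across
probes between the two members of a pair. Per-gene reproducibility is the
correlation across tumours between first- and second-sample values, with a
two-sided p from the exact t transform on $n-2$ df; the permutation
machinery lives in the differential-expression module instead, where it
tests a different hypothesis.

"Pairs clustering together" is defined as **sibling leaves**: the pair's two
samples are merged with each other before either joins anything else. This
is the strictest reading of dendrogram adjacency and is invariant to sample
input order; tie-breaks in agglomeration follow the lowest merged-cluster
index (the behaviour of classical agglomerative implementations), so the
tree is deterministic. Clustering uses all retained probes — the open
alternative, a variance-filtered subset, is not taken because the reference
figures describe clustering over the full filtered probe set.

# Paired differential expression

Per gene: $t = \bar d / (s_d/\sqrt n)$ on within-pair differences. The
permutation support is a **sign-flip test**: under the paired null each
tumour's difference is symmetric about zero, so flipping signs generates the
reference distribution without disturbing between-tumour structure. With
$n \le 10$ pairs all $2^n$ patterns are enumerated and the p-value is exact
(`#\{|t^*| \ge |t|\}/2^n`); otherwise random patterns give the standard
add-one estimate $(1 + \#)/(1 + B)$. The "multivariate permutation test" of
the classic array-tools workflow is realized as these per-gene permutation
p-values fed into Benjamini–Hochberg; the original procedure's exact
parameters are not published, and this combination reproduces its two
ingredients (permutation reference, FDR control) transparently.

Selection uses q < 0.05 and fold change > 1.25 in either direction
(reciprocal rule, matching reported negative fold changes); a screening
variant (`criterion = "p_screen"`, p < 0.005 and FC ≥ 1.25) supports
small-cohort exploratory ranking. A threshold at or beyond its no-op value
(`fdr_max >= 1`, `fc_min <= 1`) disables that filter, so boundary
configurations behave as "select everything tested" rather than tripping on
`q == 1` edge cases.

Degenerate genes (zero-variance differences) are flagged: p = 1 when the
mean difference is also zero, p = 0 otherwise — they carry certainty, not
evidence, and the flag tells the user to look.

The elapsed-time screen correlates each gene's within-pair difference with
the recorded minutes between samples; it requires a sheet that records
elapsed time and says so explicitly when given one that does not.

# Signatures

A signature score is $\sum_g w_g x_{gs} / \sum_g |w_g|$: normalizing by
$\sum|w|$ keeps scores on the expression scale whatever the weights.
Multiple probes per gene are averaged *before* weighting so that a gene
measured by three probes does not count three times; probe-level weighting
is available behind a flag. Genes absent from the platform are reported as
unmatched and never silently change the score.

Only gene sets whose memberships are public are bundled: the 13-gene
biopsy-response panel (the 14th member has no probe on the platform) and a
partial panel of commonly studied breast-cancer genes — partial because the
full 18-gene list exists only in a non-public supplement; bundling a guess
would be worse than bundling nothing. Wound-healing and immune metagenes are
user-supplied files for the same reason.

# Intrinsic subtyping

Nearest-centroid classification: each sample is assigned the subtype whose
centroid its profile correlates with best over the shared genes, Spearman by
default (classical centroid-classifier practice; Pearson available).
Expression is gene-wise median-centered across the cohort first
(switchable — the flag matters for degenerate inputs, see below). At least
half the centroid genes must be present; fewer is an error naming the
missing genes, not a silent partial classification.

The scientifically interesting output is not the label but the **margin**:
the signed difference between the LumA and LumB centroid correlations
(absolute value for group summaries). Discordant paired calls concentrate
where margins are small — the assignment was genuinely uncertain — and the
package quantifies this with median margins per concordant/discordant group
and order-statistic (binomial) 95% CIs for the median, falling back to a
bootstrap percentile interval below n = 6 where the order-statistic
construction cannot reach 95% coverage.

Systematic drift between timepoints is tested by an exact binomial test on
the contingency table's above- versus below-diagonal off-diagonal counts.

Degenerate case: if a profile has zero variance after median centering
(possible in simulation when a majority subtype is noiseless), its
correlations are undefined; the classifier warns and returns `NA` calls
rather than inventing one. Ties between centroids are broken alphabetically
and flagged.

Real clinical centroid tables are **not bundled** (they are licensed
artifacts); users supply a centroid TSV, and all tests run on synthetic
centroids.

# Cross-study comparison

Fisher's variance-stabilizing transform $z = \operatorname{atanh}(r)$ gives
$Z = (z_1 - z_2)/\sqrt{1/(n_1-3) + 1/(n_2-3)}$, two-tailed normal p. Values
are reported raw and rounded to conventional table precision (Z to 2 d.p.);
`p_from_rounded_z` is also emitted because printed tables typically compute
p from the already-rounded Z, and that is the only way their p columns
reproduce exactly. Genes missing from either study are kept as `ND` rows.

# The simulator: what it emulates and what it does not

Defaults describe the world the analyses target: 56 tumour pairs,
mostly-luminal subtype mix, $\sigma_b = 1$, $\sigma_w = 0.25$ (ICC ≈ 0.94,
whole-profile correlations ≈ 0.98, matching the observed >0.97 regime),
biopsies 20–60 minutes apart when an elapsed-time model is on, logistic
detection dropout calibrated so ordinary cohorts pass the 30% QC, and an
optional degraded-sample mode that deliberately fails it.

Two modelling choices deserve their own justification:

* **Correlated luminal centroids** (`luminal_correlation = 0.8`): the two
  luminal subtypes are molecular neighbours, and their real centroid
  profiles are strongly correlated. Independent random centroids would make
  the subtypes trivially separable and the observed LumA↔LumB flip regime
  (the dominant discordance mode, at small margins) impossible to emulate.
  0.8 puts default cohorts in the reported ~5–15% discordance range.
* **Gaussian noise on the log2 scale**: the downstream statistics are
  correlations and t tests; heavier-tailed alternatives were deferred as
  they would mostly stress-test robustness the pipeline does not claim.

What the simulator does **not** emulate: probe-level bead intensities,
scanner artifacts, RNA-quality gradients, correlated gene-gene structure
beyond the subtype centroids, or non-Gaussian biological outliers (the
heterogeneous single-tumour spikes seen in cytokine genes). A green
recovery test therefore establishes that the statistics do what they claim
under the stated model — not that real cohorts satisfy that model. The
per-gene $\sigma_w$ defaults are illustrative: real data only support
qualitative statements about narrow- versus wide-range genes.

# Numerical conventions

* Permutation and simulation seeds are mandatory everywhere; identical
  seeds give byte-identical outputs (the pipeline manifest records
  checksums to prove it).
* Quantile normalization is idempotent to 1e-12; batch centering leaves
  per-batch gene means equal to the global mean to 1e-12.
* Correlations of zero-variance vectors are `NaN` with a warning, never a
  silent drop.
* The default permutation seed (20160401) and thresholds
  (30% detection, FDR 0.05, FC 1.25, screen p 0.005) are recorded in every
  run configuration echo.

# Known limitations

* The preprocessing recipe is a reasonable reconstruction, not a certified
  reproduction, of the upstream protocol; reproducing deposited cohorts
  exactly is explicitly out of scope (`geo_reproduction_summary()` reports
  deviations instead of asserting).
* No empirical-Bayes moderation of gene variances (limma-style); with
  paired designs at n ≥ 23 the plain paired t is adequately powered and
  simpler to permute.
* The binomial asymmetry test pools all off-diagonal cells; with many
  subtypes and few discordances it is conservative.
* The exhaustive permutation path is capped at 20 pairs ($2^{20}$ patterns).
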