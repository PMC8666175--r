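---
title: "Characterizing and applying a targeted SRM/MRM assay: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing and applying a targeted SRM/MRM assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmquant)
```

## The measurement model

Targeted selected/multiple reaction monitoring (SRM/MRM) quantifies a
predefined set of proteins through surrogate tryptic peptides. Each peptide
is monitored as a handful of *transitions* (precursor/fragment ion pairs),
and each transition contributes one chromatographic peak area per run. A
stable-isotope-labeled (SIL, "heavy") synthetic copy of every peptide,
spiked at a known amount, serves as an internal standard: the ratio of the
endogenous ("light") to the heavy signal cancels most run-to-run variation
in ionization and instrument response.

`mrmquant` implements the computational side of such an assay for a panel
of 13 one-carbon metabolism enzymes monitored through 40 peptides:

1. **Assay design** — in-silico tryptic digestion and proteotypic candidate
   filtering (`digest_trypsin()`, `select_candidates()`).
2. **Assay characterization** — detection and quantification limits,
   response linearity, and multi-day variance components
   (`build_assay_report()`).
3. **Quantification** — interference screening, summed-transition ratios,
   heavy-standard normalization, and peptide-to-protein rollup
   (`flag_interference()`, `compute_ratios()`, `normalize_runs()`,
   `rollup()`).
4. **Cohort statistics** — per-protein condition models with FDR control,
   PCA, and Ward clustering (`fit_condition_model()`, `run_pca()`,
   `cluster_proteins()`).
5. **Classification** — ANOVA-ranked nested biomarker panels under
   leave-one-out cross-validation (`evaluate_panels()`,
   `final_model_report()`).

Because no processed study data are distributed in an open format, the
package ships a first-class synthetic-data module whose generators emulate
the three experiment classes of a typical assay-development study —
calibration dilution series with blanks, a days-by-replicates design, and a
three-class clinical cohort — with known ground truth, so that every
downstream stage is testable end to end.

## The synthetic-data generators

### Noise model

Measured peak areas are modeled as

\[
A = s \cdot c \cdot \varepsilon + b, \qquad
\varepsilon \sim \mathrm{LogNormal}\!\left(-\tfrac{\sigma^2}{2},\, \sigma\right),
\quad b \sim \max\{0, \mathcal N(\mu_b, \sigma_b^2)\},
\]

where \(s\) is the peptide's response slope (area units per fmol), \(c\)
the spiked amount, \(\varepsilon\) a mean-one multiplicative lognormal
noise term with level-dependent coefficient of variation (CV), and \(b\)
an additive background signal truncated at zero (areas are nonnegative;
blanks carry background only). The CV is specified as a map from
concentration to CV and interpolated on the log10 concentration scale; the
default rises from ~4% at high load to 30% at 0.5 fmol, reproducing the CV
inflation near the detection limit that is characteristic of real dilution
series. The true distributional form of SRM measurement noise is not
known; the lognormal is a documented stand-in, chosen because area noise
is multiplicative and strictly positive.

### Defaults as study conditions

The generator defaults encode the emulated study design rather than tuning
knobs: dilution levels 0.5–1000 fmol with the light counterpart fixed at
100 fmol and three blank runs; a replicate design of 3 injections × 5 days
at 5/50/500 fmol heavy with light fixed at 30 fmol and variance components
of 5% (within-day) and 8% (between-day) on the log scale; and a clinical
cohort of 28 controls, 15 cirrhosis, and 19 hepatocellular carcinoma (HCC)
samples. Clinical effects place one protein cluster (GNMT, CBS, CGL,
MAT1A, BHMT, SHMT1, SHMT2) down in disease and the other (AHCY, DHFR,
MAT2A, MAT2B, MTAP, METH) up, with the cirrhosis effect set to half the
HCC effect so that cirrhosis is an intermediate condition. Where the
emulated study reports no value (per-peptide slopes, background levels,
clinical effect sizes, residual noise), defaults were fixed once at values
a targeted-proteomics practitioner would consider realistic: slopes of
1000–4000 area units/fmol, background placed so blank-derived detection
limits fall in the low-fmol range, an HCC effect of 1.2 log2 units with
residual SD 0.5.

The generators emulate *signal magnitudes and their variance structure*
only. They do not simulate chromatographic peak shapes, retention-time
drift, missed integrations, or matrix-dependent ionization suppression, so
green tests demonstrate the correctness of the computations, not the
field performance of an instrument method.

## Assay figures of merit

* **LLOD.** The detection threshold is the mean blank signal plus three
  blank SDs, converted to concentration through the fitted signal response
  and floored at zero. When blanks carry no signal at all, the fallback
  threshold is three SDs of the lowest spiked level's signal — with no
  mean term, since a blank-free estimate has no meaningful baseline.
* **LLOQ.** The lowest level whose replicate CV is below 20% *with all
  higher levels also below 20%*. The stricter monotone form prevents a
  random dip in a noisy low level from defining a spurious LLOQ. Because
  LLOD and LLOQ use different arithmetic, LLOQ can legitimately fall below
  LLOD; the report keeps both and raises a flag rather than reconciling
  them.
* **Linearity.** Ordinary least squares of the mean measured ratio against
  the nominal level; at protein scope the peptide ratios are first
  averaged per level. The acceptance bound on \(R^2\) (default 0.96) is a
  configurable parameter of the QC workflow.
* **CV components.** Intra-assay CV is the mean over days of the
  within-day replicate CV; inter-assay CV is the mean over injection index
  of that injection's across-day CV; the total CV is their quadrature sum
  \(\sqrt{\mathrm{intra}^2 + \mathrm{inter}^2}\). CVs are computed as
  SD/mean on the ratio scale (not the log scale), matching conventional
  assay-validation practice, and a peptide is accepted only when all three
  CVs are below 20% at every assayed level. Note that the sample CV of
  strongly skewed lognormal noise is biased low at small replicate counts;
  simulations that probe threshold-crossing behavior therefore need either
  a clear CV separation between adjacent levels or generous replication.

## Quantification choices

* **Interference screening.** The study this package emulates excluded
  interfered transitions by manual inspection. The automated surrogate
  compares each transition's light/heavy ratio with the within-peptide
  median transition ratio and excludes deviations beyond a 2-fold
  tolerance, never removing the last transition. This is majority voting:
  it assumes at most a minority of a peptide's transitions are
  contaminated in any one run, and it cannot (by design) flag anything for
  single-transition peptides.
* **Ratios.** Summed light areas over summed heavy areas (over the
  retained transitions), rather than a mean of per-transition ratios: the
  sum weights transitions by signal and is therefore robust to
  weak-transition noise.
* **Normalization.** The run-level technical factor is the median over
  peptides of the run's log2 heavy area minus that peptide's across-run
  mean. Subtracting it levels the constant heavy spikes across runs.
  A full two-way (peptide + run) least-squares fit is available via
  `method = "least_squares"` and agrees with the median estimator on
  symmetric data; the median is the default because with at most 40
  peptides a few aberrant heavy measurements would leverage a
  least-squares fit.
* **Rollup.** Protein estimates are weighted sums of peptide abundances
  with weights renormalized over the non-missing peptides of each sample.
  Default weights are inversely proportional to each peptide's variance
  across samples. With few peptides per protein, peptide-specific noise
  variance cannot be separated from shared biological variance; since the
  biological component is common to all peptides of a protein, it shifts
  all weights toward equality and the ordering by noise is preserved. An
  explicit equal-weight scheme is also provided. Below-LLOD clinical
  signals are treated as missing, never as zero.

## Cohort statistics

Per protein, a least-squares model of normalized log2 abundance on
clinical condition provides the omnibus condition F-test and the three
pairwise contrasts (HCC−control, cirrhosis−control, HCC−cirrhosis) with
t-test p-values from the pooled residual variance. In this design each
subject contributes one sample, so no subject term is fitted; when a
`subject_id` column with repeated samples is supplied, the model adds a
blocking factor. Multiple testing is controlled with Benjamini–Hochberg
q-values computed across proteins separately within each contrast family,
matching how per-contrast significance calls are usually reported.
Zero-variance proteins return p = 1 with a flag rather than an error.

For PCA and clustering the matrix must be complete; missing cells are
imputed with half the protein's minimum observed value, reflecting the
left-censored (below-LLOD) missingness mechanism. Proteins are centered
and scaled, PCA uses the exact singular value decomposition, and protein
profiles are clustered by Ward's method on Euclidean distances
(`hclust(method = "ward.D2")`), with the cluster count a user parameter
(default 2) since dendrogram cutting is ultimately a judgment call.

## Classification protocol

Proteins are ranked by one-way ANOVA p-value (ties broken by name) and
nested panels of the top 1..k proteins are evaluated with four algorithms
— LDA, QDA, multinomial logistic regression, and random forests — under
leave-one-out cross-validation (LOOCV), all with fixed default
hyperparameters (500 trees for the forest, no tuning); model complexity is
controlled by panel size alone. By default the ANOVA ranking is recomputed
inside each training fold so that feature selection never sees the
held-out sample; `rank_once = TRUE` reproduces the simpler rank-on-all-data
protocol. The two options are both legitimate published practices and can
differ noticeably at these sample sizes, which is why both are exposed.
QDA requires every training class to have more samples than the panel has
dimensions; folds violating this are skipped and recorded rather than
silently regularized. The final model report pools the LOOCV held-out
class probabilities into a confusion matrix, out-of-sample accuracy, and
per-class one-vs-rest ROC curves with trapezoidal AUC.

## Numerical conventions

* All CSV writers serialize doubles with 17 significant digits, so
  read∘write is the identity on numeric fields.
* Every generator takes an explicit seed, uses it locally, and restores
  the caller's RNG state; the pipeline derives stage seeds from a single
  master seed at fixed offsets, making full runs byte-reproducible.
* Degenerate inputs fail loudly and specifically: fewer than 3 blanks,
  single replicates, fewer than 3 levels, zero calibration slope,
  single-class label sets, and k larger than the protein count are all
  rejected with dedicated errors; zero-variance proteins degrade to
  defined results (p = 1, rank last, excluded from PCA with a warning).

## Problem sizes used in the test suite

The packaged tests exercise the full 40-peptide/13-protein panel for
single-run checks and scale replication to the precision each property
needs: 1000 null simulations for type-I error calibration, 200 seeds for
effect recovery, 200 label permutations for the classification null, 100
seeds for LLOQ recovery, 2000 simulated days for variance-component
recovery, and 500 random inputs each for the digestion and
Benjamini–Hochberg brute-force oracles. These sizes keep the whole suite
in the minutes range on a single core while leaving Monte-Carlo error well
inside the asserted tolerances.

## Known limitations

* Areas are inputs: peak detection, integration, and manual curation live
  upstream in instrument software and are out of scope.
* The interference screen needs at least two transitions and assumes
  minority contamination; correlated interference across most transitions
  of a peptide is indistinguishable from signal.
* The inverse-variance rollup weights are estimated, not known; for
  two-peptide proteins with strong shared biological variation they
  approach equal weights.
* The synthetic cohort draws independent Gaussian residuals per peptide;
  real cohorts show heavier tails and correlated technical structure, so
  classifier accuracies on synthetic defaults should not be read as
  expected clinical performance.
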