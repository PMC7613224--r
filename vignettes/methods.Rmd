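---
title: "Methods: synthetic plasma NMR cohorts and validated OPLS-DA classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic plasma NMR cohorts and validated OPLS-DA classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabodx)
```

## Scope

`metabodx` implements an end-to-end workflow for asking whether a
one-dimensional ^1^H-NMR plasma profile can discriminate patients with a
solid tumor from cancer-free patients, and — just as importantly — for
*validating* that claim honestly. The package contains:

1. a parametric generator of realistic plasma spectra with a known,
   controllable class difference (the "truth" is available, so every
   downstream statistic can be audited);
2. spectral preprocessing (chemical-shift referencing, fixed-width
   bucketing with water exclusion, Pareto scaling);
3. an OPLS-DA implementation written from first principles (NIPALS, with
   internal cross-validated selection of the number of orthogonal
   components, and VIP scores);
4. external validation machinery (repeated stratified cross-validation,
   permutation null distributions, Kolmogorov–Smirnov comparison);
5. diagnostic metrics (ROC/AUC, Wilson intervals, Fisher exact test,
   DeLong AUC comparison) and a univariate follow-up panel.

This vignette documents the model, the defaults and their rationale, and
the numerical choices, so that results are interpretable without reading
the source.

## The spectral generator

### Line shapes

Each metabolite resonance is a Lorentzian, the natural line shape for
liquid-state NMR. A resonance at position $\delta_0$ with full width at
half maximum $\mathrm{fwhm}$ contributes

$$L(\delta) = \frac{1}{\pi}\,
  \frac{\mathrm{fwhm}/2}{(\delta-\delta_0)^2 + (\mathrm{fwhm}/2)^2},$$

which integrates to exactly 1 over the real line. Because every peak has
unit area, a metabolite's *integral* in the spectrum is proportional to
its concentration times the sum of its relative multiplet amplitudes —
integrals, not peak heights, carry the quantitative signal, exactly as in
real NMR. Broad macromolecular envelopes (lipoproteins, albumin lysyl)
are modeled the same way with large linewidths.

### Peak library

`build_peak_library()` ships 30 plasma species: high-concentration
metabolites (glucose, lactate, alanine, glutamine, ...), the composite
lipoprotein CH~3~/CH~2~ envelopes, N-acetyl glycoprotein signals (NAC1,
NAC2), and low-abundance amino acids. Each entry records multiplet
positions (ppm), relative amplitudes, a linewidth, and a baseline plasma
concentration in relative units. Positions and multiplicities follow
standard plasma assignment tables; concentrations are order-of-magnitude
realistic rather than assay-calibrated, which is sufficient because the
classifier operates on relative, Pareto-scaled features.

### Biological and instrumental variation

For sample $i$ and metabolite $m$, the concentration is log-normal:

$$c_{im} = \mathrm{baseline}_m \cdot 2^{\beta_m y_i / 2} \cdot
  e^{\sigma Z_{im}}, \qquad Z_{im} \sim N(0, 1),$$

where $y_i \in \{-1, +1\}$ is the class label, $\beta_m$ the log2 fold
change of the class effect, and $\sigma$ the biological coefficient of
variation (default 0.25, typical of plasma metabolites). Writing the
effect as $2^{\beta_m y_i/2}$ makes the *ratio of class medians* equal
$2^{\beta_m}$ regardless of $\sigma$. On top of this, every metabolite's
multiplet is jittered in position by $N(0, 0.002^2)$ ppm per sample
(pH/ionic-strength sensitivity), and i.i.d. Gaussian noise is added to
the intensity trace.

The default effect panel moves six metabolites at $|\beta| = 0.7$:
lipoprotein CH~3~, lipoprotein CH~2~ and saturated lipid down in cancer,
glucose, NAC1 and threonine up. This mimics the published plasma-NMR
cancer signature (lipid depression, acute-phase glycoprotein elevation)
while remaining fully synthetic.

### What the generator does *not* emulate

Water suppression artifacts, baseline roll, phasing errors, J-coupling
fine structure, peak-shape asymmetry, and between-batch drift are all
absent. The generator is designed to validate the *statistical* pipeline
— separability, overfitting control, calibration of null distributions —
not to train models transferable to real instruments.

## Preprocessing

* **Referencing.** `reference_to_lactate()` locates the lactate methyl
  doublet in a 1.20–1.45 ppm window and shifts the axis so its center
  sits at 1.33 ppm. Plasma lacks TSP in many protocols; lactate is a
  robust endogenous anchor. A minimum signal-to-noise of 5 guards against
  locking onto noise; failures are recorded, not silently ignored.
* **Bucketing.** `bucket_spectrum()` integrates the spectrum into
  0.01-ppm half-open buckets over 0.20–9.68 ppm, skipping the residual
  water region [4.50, 5.00) ppm — 898 buckets. Integrals are exact
  trapezoid integrals with edge interpolation, so bucketing is linear in
  the intensity trace and adjacent buckets tile the axis without overlap
  or gaps. Fine bucketing plus referencing replaces peak alignment.
* **Scaling.** Pareto scaling, $(x - \bar{x}) / \sqrt{s}$, the standard
  compromise for NMR metabolomics: unit-variance scaling explodes noise
  buckets, no scaling lets the lipid envelopes dominate. The scaler is
  always fit on training data only and then *applied* to held-out data
  (`fit_pareto()` / `apply_pareto()`); no function in the package refits
  scaling on test samples. No integral (total-area) normalization is
  applied by default: synthetic spectra share a common acquisition scale,
  and dilution variation is not part of the generative model.

## OPLS-DA

`fit_opls()` implements orthogonal projections to latent structures for
a single binary response via NIPALS. With $X$ ($n \times J$, centered by
Pareto scaling) and $y \in \{-1,+1\}^n$:

1. predictive weight $w \propto X^\top y$, normalized;
2. for each orthogonal component: $t = Xw$, loading
   $p = X^\top t / t^\top t$, orthogonal weight
   $w_o \propto p - (w^\top p)\, w$, orthogonal score $t_o = X w_o$,
   orthogonal loading $p_o = X^\top t_o / t_o^\top t_o$, deflation
   $X \leftarrow X - t_o p_o^\top$;
3. final predictive score $t = Xw$ on the deflated matrix and regression
   coefficient $b = y^\top t / t^\top t$.

Prediction removes the stored orthogonal components from new data and
returns $b\, t_{\text{new}}$. Because $w$ is computed once from the
undeflated matrix, VIP scores are invariant to the orthogonal depth,

$$\mathrm{VIP}_j = \sqrt{J}\, |w_j|, \qquad
  \tfrac{1}{J}\sum_j \mathrm{VIP}_j^2 = 1,$$

and a bucket is called *significant* when VIP > 2 — a deliberately
conservative cut (2 is often used where 1 is the conventional floor)
appropriate when hunting a small discriminatory panel among ~900 buckets.

### Choosing the number of orthogonal components

$Q^2 = 1 - \mathrm{PRESS}/\mathrm{SS}$ is estimated by stratified 7-fold
internal cross-validation for every depth 0–9, and
`select_n_orthogonal()` takes the argmax, breaking ties toward fewer
components. Argmax (rather than a "first drop" heuristic) was chosen
because it is deterministic, simple to audit, and with the tie-break
toward parsimony it never adds components that do not measurably help.
All depths are evaluated in a single deflation pass (`opls_path()`),
which is algebraically identical to refitting at each depth.

## Validation design

The cohort is split by *referral order* (first two thirds modeling, last
third test), mimicking a temporal split — the test set is never touched
until the threshold and model are frozen.

* **External CV.** `external_cv()` runs repeated (default 10×) stratified
  10-fold cross-validation on the modeling set. Everything — Pareto
  scaling, orthogonal-depth selection, the model itself — is refit inside
  each training fold, so the held-out fold is genuinely blind. Fold
  metrics (sensitivity, specificity, accuracy, balanced accuracy) form
  the real performance distribution.
* **Permutation null.** `permutation_null()` shuffles the class labels
  and reruns the identical CV procedure (default 20 permutations). If
  the pipeline leaked information anywhere, the null would drift away
  from chance — a built-in self-audit.
* **Comparison.** `ks_compare()` applies the two-sided
  Kolmogorov–Smirnov test (via `stats::ks.test`) to the real vs null
  metric distributions. A significant D confirms the real distribution
  is not a relabeling artifact.

### Classification threshold

The decision threshold is chosen from the ROC of the *pooled
out-of-fold* modeling scores (mean over repeats), at the point closest
to the top-left corner (ties resolved toward higher specificity —
appropriate at 8% prevalence, where false positives are costly). Using
cross-validated rather than refit scores avoids the optimism of
thresholding on training output; `run_study(threshold_source = "fit")`
exposes the alternative for comparison.

### Test-set evaluation

The independent test set is evaluated exactly once: confusion table,
sensitivity/specificity/PPV/NPV/accuracy/balanced accuracy/F1, Wilson
score intervals (closed form; preferred over Wald for the small positive
class), one-sided Fisher exact test of association, and the test-set
ROC. Modeling vs test AUC is compared with an unpaired DeLong Z test
(placement-value variances, normal reference); agreement of the two AUCs
indicates the model did not overfit its development data.

## Univariate follow-up

For every metabolite whose library resonances overlap a VIP-significant
bucket, `metabolite_integrals()` sums the *unscaled* bucket integrals
over that metabolite's resonance windows, and the panel reports the
cancer/noncancer fold change with a Student t test. This deliberately
retraces the classical univariate route on the same data, as a sanity
check that the multivariate signature corresponds to interpretable
concentration differences.

## Known limitations

* **Low-abundance effect metabolites can evade VIP.** Pareto-scaled VIP
  weights a bucket by correlation × √(standard deviation). A metabolite
  with a strong *relative* effect but a small absolute integral
  (threonine in the default panel, baseline ~1.2 against lactate ~10 in
  the same region) produces buckets whose √sd term keeps VIP below the
  conservative cut of 2 even when its univariate t test is clearly
  significant. This is a real property of Pareto-VIP at these study
  conditions, not an implementation artifact: the high-abundance panel
  members (lipoproteins, glucose, NAC1) are recovered reliably while
  threonine typically scores VIP ≈ 1–1.5. Lowering the cut to the
  conventional 1, or unit-variance scaling, recovers it at the price of
  more false-positive buckets.
* The generator's noise is i.i.d. Gaussian; real NMR noise is colored by
  apodization, so signal-to-noise figures do not transfer literally.
* `ks.test` emits ties warnings when CV folds produce identical metric
  values (common for small folds); p-values are then approximate.
* Runtimes scale with spectrum resolution; analyses here use 4096-point
  axes, which keep every bucket ≥ 4 raw points at 0.01 ppm. The default
  `default_ppm_axis()` resolution (32768) matches real acquisitions but
  is slower to simulate.

## Reproducibility

Every stochastic function takes an explicit seed and restores the global
RNG state on exit (`with_seed()`). Nested procedures derive child seeds
deterministically (`child_seed()`), so, e.g., repeat 3 of external CV is
reproducible in isolation. The `analysis/` scripts run the full study at
a fixed seed; `scripts/acceptance.R` emits a JSON summary of the key
quantities for any seed.
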