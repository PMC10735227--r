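---
title: "Triangulating genetic liability and the circulating metabolome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating genetic liability and the circulating metabolome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtri)
```

## The problem

Observational associations between circulating metabolites and colorectal
cancer are hard to interpret: a metabolite may cause disease, may respond
to incipient disease (or to genetic liability to it), or may merely share
confounders with it. `mrtri` implements a triangulation strategy that
attacks the question from three genetically informed angles:

1. **A GRS-metabolome scan.** A weighted genetic risk score (GRS) for
   disease liability, built from GWAS-significant variants with external
   log-odds weights, is regressed against each circulating metabolite
   measured repeatedly across early life. Because germline genotype is
   fixed at conception, an association indicates that liability (not
   manifest disease) shifts the metabolite.
2. **Reverse two-sample Mendelian randomization (MR).** Disease liability
   is the exposure and each metabolite the outcome, using independent
   GWAS summary statistics for both sides.
3. **Forward two-sample MR.** Each metabolite is the exposure and disease
   the outcome, giving odds ratios per SD of metabolite.

A metabolite flagged in the forward direction and in at least one
liability-driven stream, with consistent directions everywhere, is a
*consistent causal candidate*. A metabolite flagged only in the
liability-driven streams behaves like a *liability marker*: predictive of
later disease, but without evidence that intervening on it would change
risk (circulating cholesterol and apolipoprotein B show this pattern in
the motivating application).

The real data behind such analyses — individual-level cohort genotypes
and NMR metabolite panels, and case–control consortium GWAS — are managed
access. The package therefore ships a synthetic-data module that
generates all three kinds of input with the statistical structure the
methods assume, and every quantitative claim in the test suite is made
against those generators' known truth.

## Genetic risk scores

Candidate variants are pruned by greedy LD clumping: candidates are
visited in order of ascending p-value and kept only if their r² with
every previously kept variant is at or below the threshold (default
0.001). Ties in p are broken by lexicographic variant id so that results
are reproducible regardless of input order. The LD matrix is an explicit
input; the package does not compute LD from a reference panel.

The raw score of individual $i$ is

$$s_i = \frac{1}{m_i}\sum_{j} w_j g_{ij},$$

with $w_j$ the external log-odds weight, $g_{ij} \in [0,2]$ the effect
allele dosage, and $m_i$ the number of variants with non-missing dosage
for that individual. Dividing by the per-individual non-missing count
(rather than the full panel size) keeps scores comparable under sporadic
missingness; a strict mode dividing by the full count, and an undivided
log-odds sum, are both available (`denominator` argument of
`score_grs()`).

Two scales matter downstream:

* the **log-odds sum** (`score_sum` in `grs_table()`) is the individual's
  genetic liability in log-odds units. Regression slopes on this scale,
  multiplied by $\ln 2 = 0.693$, read as *SD of metabolite per doubling
  of the odds of disease* — the per-doubling scale used in all reports.
  Multiplying a per-unit-log-odds slope by $\ln 2$ is only interpretable
  as "per doubling" on the log-odds scale, which is why the scan
  regresses on the raw sum rather than on the z-scored score;
* the **z-scored score** (`score_z`) is reported descriptively.

Gene-region exclusion (`exclude_region()`) supports the standard
sensitivity analysis of dropping variants in the FADS cluster
(FADS1/2/3), whose alleles alter lipid metabolites directly rather than
through disease liability. Region tags are supplied as a variant-to-tag
map or a `region` column; the package deliberately does no coordinate
arithmetic, since region boundaries are an analysis choice, not a fact
the data carry.

## Phenotype preparation and the scan

Metabolite concentrations are normalised by rank-based inverse normal
transformation: the value with rank $r$ of $n$ maps to
$\Phi^{-1}\!\big((r - c)/(n - 2c + 1)\big)$ with the Blom offset
$c = 3/8$ (configurable); ties take average ranks so the transform is
deterministic. Transformation is applied within time point, and analysis
is complete-case per time point, matching the differing sample sizes of
repeated clinic visits.

Each metabolite–time point pair is fit by ordinary least squares with
heteroskedasticity-consistent (HC1) sandwich standard errors — the
conventional "robust" flavour; HC3 is available by flag. p-values use the
normal approximation, as is standard for large-sample genetic
association work. Estimates, SEs, and interval bounds are then multiplied
by $\ln 2$; the Wald statistic is scale-invariant, so p-values are
unaffected by the rescaling.

Benjamini–Hochberg adjustment is applied within each time point ×
sensitivity family across metabolites, mirroring per-age presentation of
such scans; adjusted p < 0.05 is used as the (explicitly heuristic)
association flag.

## Two-sample MR estimators

All estimators consume a harmonized instrument table. Harmonization
aligns outcome rows to the exposure's effect allele, flipping the
outcome beta and complementing its frequency where the allele labels are
swapped (on either strand). Palindromic variants (A/T, C/G) are aligned
by allele frequency when both sides are informative and dropped when
either frequency is missing or falls in the ambiguity window
(0.42–0.58, configurable); incompatible allele pairs and instruments
absent from the outcome are dropped with logged reasons. Proxy-variant
lookup is not implemented.

With per-variant Wald ratios $\hat\beta_j = b_{yj}/b_{xj}$ and
first-order SEs $s_j = s_{yj}/|b_{xj}|$:

* **IVW (multiplicative random effects).** Weights $w_j = s_j^{-2}$;
  estimate $\hat\beta = \sum w_j\hat\beta_j / \sum w_j$; Cochran's
  $Q = \sum w_j(\hat\beta_j - \hat\beta)^2$ on $L-1$ df; the SE is the
  fixed-effect SE inflated by $\max\{1, \sqrt{Q/(L-1)}\}$, so it never
  falls below the fixed-effect SE. Unbiased only when no instrument is
  horizontally pleiotropic.
* **Weighted median.** Ratios are sorted; with standardized weights
  $w'_j$ the cumulative midpoint is $s_j = \sum_{k \le j} w'_k - w'_j/2$
  and the estimate interpolates linearly at $s = 0.5$. Consistent while
  at least half the weight comes from valid instruments.
* **Weighted mode.** The maximiser of a Gaussian-kernel, inverse-variance
  weighted density over the ratios, evaluated on a fixed 512-point grid
  spanning the ratio range ± 3 bandwidths. Bandwidth
  $h = \varphi \cdot 1.4826 \cdot \mathrm{MAD}$, falling back to
  $\varphi$ times the weighted SD when the MAD is zero; $\varphi = 1$ by
  default. Consistent under the zero-modal-pleiotropy assumption
  (ZEMPA): the largest group of instruments shares zero pleiotropy, even
  if it is a minority of the weight.

Median and mode SEs come from a parametric bootstrap (default 1,000
resamples of the per-variant betas from their reported normal sampling
distributions, seeded); p-values use the normal approximation on the
bootstrap SE. Setting `n_boot = 0` returns point estimates only, which
the simulation drivers use where only means and biases are needed.

Per-variant instrument strength is $F_j = (b_{xj}/s_{xj})^2$, with a
warning below the conventional minimum of 10.

Direction-specific scaling: reverse-direction estimates are multiplied by
$\ln 2$ (per doubling of liability, applied after estimation; the choice
of applying it before or after FDR is immaterial to p-values); forward
estimates are exponentiated to odds ratios per SD of metabolite, with the
interval bounds exponentiated and the SE kept on the log scale.

## Triangulation

"Consistent evidence across approaches" is never formalized in applied
triangulation studies; `classify_consistency()` pins down one explicit
operationalization. Each stream contributes a direction only where its
FDR flag passes: the scan's sign (from the time point with the smallest
adjusted p, primary sensitivity setting), the reverse-MR sign, and the
forward-MR side of OR = 1 (IVW primary, with a concordance note when the
other methods disagree in sign). Conflicting flagged directions are
`inconsistent`; forward evidence plus at least one flagged liability
stream, all same-signed, is a `consistent-causal-candidate`; liability
streams without forward evidence are `liability-marker-only`; forward
alone is `forward-only`; nothing flagged is `insufficient`. The strict
reading — requiring *all three* streams — was considered and relaxed for
the one undefined cell (forward plus exactly one liability stream,
same-signed): positive evidence in two independent designs with no
contradiction is closer in spirit to a candidate than to either
single-stream class. Classes partition the metabolite set; metabolites
missing from a stream are classified from what is available and marked,
never dropped.

## The synthetic-data module

What it emulates:

* **Variant panels** (`gen_variant_panel()`): Hardy–Weinberg dosages,
  LD blocks realized through a Gaussian copula over latent allele
  scores. The latent correlation is solved numerically (from the
  bivariate-normal orthant probability) to hit the target allele-level
  correlation after dichotomization, and variants within a correlated
  block share one minor-allele frequency — tightly linked variants have
  near-identical frequencies in real data, and unequal thresholds would
  otherwise attenuate the realized r² well below target. The LD matrix
  handed to clumping is the *empirical* r² of a seeded reference sample
  (n = 2,000), so tests are self-consistent; cross-block entries and
  zero-target blocks are exactly zero by construction. Observed betas
  are the true liability weights plus small estimation noise, with SEs
  scaled so that reported p-values fall in a genome-wide-significant
  band.
* **Cohorts** (`gen_cohort()`): liability $S_i = \sum_j w_j g_{ij}$ in
  log-odds units; metabolite
  $M = \theta_k S/\ln 2 + \beta_{sex}\,\mathrm{sex} + \beta_{age}\,
  \mathrm{age}_c + \varepsilon$, so $\theta_k$ is exactly the SD-unit
  effect per doubling of liability the scan estimates. When
  standardization is requested the noise SD is set to
  $\sqrt{1 - \text{explained variance}}$, giving near-unit marginal SDs
  without rescaling $\theta_k$. Defaults: sex effect 0.1 SD, age effect
  0.01 SD/year — small covariate signals of the size seen in adolescent
  metabolome data.
* **Two-sample pairs** (`gen_two_sample()`): instruments are reported
  with the exposure-raising allele as effect allele (the usual
  convention), so true exposure effects are positive and directional
  pleiotropy stays directional on the Wald-ratio scale. Outcome betas
  are $\theta b_{xj}^{true} + \alpha_j + $ noise, with $\alpha_j = 0$
  for valid instruments, $N(0, \sigma_p)$ for balanced pleiotropy and
  $N(+\sigma_p, \sigma_p/2)$ for directional. `gen_reverse_set()` and
  `gen_forward_set()` assemble coherent multi-trait families (one
  exposure, many outcomes, and vice versa) so `run_mr()` can be
  exercised exactly as in a real analysis.

What it does **not** emulate: population structure and relatedness (the
real analyses adjust for principal components), imputation uncertainty,
case–control ascertainment, non-European ancestry LD patterns, binary
disease status (liability is used as a continuous score throughout), and
any realistic metabolite correlation structure — metabolites are
generated independently given the liability score, whereas real NMR
panels are heavily inter-correlated. Passing tests therefore demonstrate
the estimators' correctness and calibration under the stated generative
models, not robustness to those unmodelled features.

## Study conditions used in the validation runs

The simulation drivers (`calibration_experiment()`,
`pleiotropy_experiment()`, `scan_recovery_experiment()`,
`triangulation_recovery_experiment()`) fix the following conditions,
chosen once as realistic for the setting:

* Calibration: 500 replicates, 50 instruments, $\theta = 0.1$, exposure
  SE 0.01 (per-variant F ≈ 25–225, bracketing the F ≈ 36–40 typical of
  disease GRS instruments), outcome SE 0.05.
* Pleiotropy ordering: 40% directionally invalid instruments,
  $\sigma_p = 0.1$ and outcome SE 0.02, so pleiotropic ratio shifts
  (~1 per unit exposure) are well separated from valid-ratio sampling
  noise; with comparable noise the ordering still holds but the margin
  shrinks toward sampling error, which would test luck rather than the
  estimators.
* Scan recovery: 200 cohort replicates of n = 5,000 with a 65-variant
  panel, 20 causal metabolites at $\theta = 0.05$ SD per doubling and
  20 nulls — effect sizes chosen for testability (the variance a real
  disease GRS explains in adolescent metabolites is not public), with
  Monte-Carlo SEs small enough to detect a relative bias of ~7%.
* End-to-end triangulation: 5 causal metabolites of 15, effects 0.15
  with alternating signs in all three streams, n = 3,000, 60-SNP panel
  (weight SD 0.1), 40 instruments per MR trait — strong enough that the
  FDR flags are near-deterministic, so candidate recovery tests the
  plumbing and classification logic, not threshold luck.

Numerical choices worth knowing: the weighted-mode grid has 512 points
(estimates are reported to within half a grid step; with 3 instruments
at ratios {0.1, 0.1, 0.1, 0.9} and equal weights the mode lands at
≈ 0.12, pulled off the majority cluster by the wide SD-fallback
bandwidth — kernel smoothing, not an error); zero-variance inputs to
`zscore()` and all-tied inputs to the rank transform are errors rather
than silent zeros; a single instrument degrades IVW to the Wald ratio
with a labelled method string; Wald p-values throughout use the normal,
not t, reference.

## Limitations

Beyond the generator's idealisations listed above: no MR-Egger, Steiger
filtering, or multivariable MR (deliberately out of scope); no
proxy-instrument lookup; FDR families are per time point (a pooled
option exists) and the choice is consequential when time points differ
in power; and the triangulation classes are an operationalization — the
boundaries (notably the FDR < 0.05 flag heuristic) are conventions, not
discoveries.
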