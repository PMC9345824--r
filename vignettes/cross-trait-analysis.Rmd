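---
title: "Cross-trait genetic analysis from GWAS summary statistics: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-trait genetic analysis from GWAS summary statistics: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosstraitr)
```

# What the package does

`crosstraitr` dissects the shared genetic architecture of two complex
traits using nothing but GWAS summary statistics and an LD reference. The
motivating application is the relationship between type 2 diabetes /
glycaemic traits and polycystic ovary syndrome (PCOS), where the question
is whether the observational association reflects shared biology
(horizontal pleiotropy), causation (vertical pleiotropy), or both, and
how much of either survives adjustment for BMI. The same machinery
applies to any trait pair.

The workflow has five stages, each usable on its own:

1. **Overall genetic correlation** (`estimate_h2`, `estimate_rg`):
   LD-score regression.
2. **Local genetic correlation** (`local_correlation_scan`): per-region
   heritability and covariance through a truncated eigendecomposition of
   regional LD.
3. **Cross-phenotype meta-analysis** (`cpassoc_scan`): per-SNP
   homogeneous and heterogeneous-effects statistics, pleiotropic-SNP
   screening, greedy LD clumping, four-category locus classification.
4. **TWAS** (`twas_scan`, `intersect_significant`): expression–trait
   association from precomputed weights, per-tissue BH-FDR, cross-trait
   intersection of significant genes.
5. **Bidirectional Mendelian randomisation** (`bidirectional_mr`,
   `mr_battery`): IVW, MR-Egger (+SIMEX), weighted median, Cochran's Q,
   MR-PRESSO, Steiger filtering, leave-one-out, instrument strength, and
   a closed-form power calculation.

`run_pipeline()` chains the stages on a simulated trait pair and writes
one table per stage plus a provenance block.

# Models and estimators

## Summary statistics and harmonization

A `sumstats` table carries per-SNP effect allele A1, other allele A2,
effect `beta` (log-OR for binary traits), `se`, `p`, and sample size.
Internal consistency is enforced on read: the z-score implied by the
p-value must match `|beta/se|` within `max(0.1, 5%)` (GWAS sources round
differently; rows beyond that are dropped and counted). Positions are
1-based on build 37; region intervals are half-open `[start, end)`.

`harmonize_pair()` aligns trait 2 to trait 1's effect allele: swapped
alleles flip the sign of `beta` and the allele frequency, strand
complements are matched after complementing. Palindromic SNPs (A/T, G/C)
cannot be resolved by letters. We resolve them by allele frequency when
both studies' frequencies are informative, and always drop them when
either frequency lies in `[0.42, 0.58]` (window half-width 0.08,
common practice) or is missing. A strict `drop_palindromic = TRUE` mode
removes them entirely, as a sensitivity analysis would. The default
pipeline keeps unambiguous palindromic SNPs because wholesale removal
costs instruments without a demonstrated bias at these frequencies.

## LD-score regression

For trait *t* with LD scores $\ell_j = \sum_k r_{jk}^2$, the expected
association chi-square is
$E[\chi^2_j] = 1 + a + n\,h^2 \ell_j / m$. `estimate_h2()` regresses
$\chi^2_j$ on $n \ell_j / m$ with a free intercept; the slope estimates
$h^2$. Weights are the standard variance-stabilizing form
$1/(2 (1 + n h^2 \ell_j/m + a)^2 \ell_j)$, plugged in from a first-pass
inverse-LD-weighted fit (two-pass scheme). The bivariate regression of
$z_{1j} z_{2j}$ on $\sqrt{n_1 n_2}\, \ell_j/m$ yields the genetic
covariance; its intercept absorbs sample overlap. Uncertainty comes from
a delete-one-block jackknife over 200 genomically contiguous blocks by
default (the convention of the reference implementation); the full ratio
$r_g = \rho_g / \sqrt{h^2_1 h^2_2}$ is re-estimated in every deletion.
SNPs with $\chi^2 > \max(80, 0.001\,n)$ are removed before regression
(outlier-locus QC). Estimates are **not** clamped to $[-1, 1]$:
estimator noise can exceed the bounds and truncation would bias
downstream use, so out-of-range values are flagged instead. When either
heritability estimate is nonpositive, $r_g$ is undefined and returned as
`NA` with a flag rather than an exception.

Two numerical notes. First, the intercept is identified by the *spread*
of LD scores; with a nearly flat $\ell$ profile the extrapolation to
$\ell = 0$ is ill-posed. The synthetic panels therefore mix block
strengths (see below). Second, because the second-pass weights are
estimated from the same data, the intercept carries a small upward
finite-sample bias that is visible at a few thousand SNPs and negligible
at the 10,000-SNP scale the tests use.

## Local genetic correlation

Within a region with LD matrix $R$ and z-vector $z$, local heritability
uses the truncated eigen-pseudoinverse
$R_k^{+} = \sum_{i \le k} u_i u_i^{\mathsf T}/\lambda_i$:
$\hat h^2_{loc} = (z^{\mathsf T} R_k^{+} z - k) / (n - k)$, and the local
covariance of two traits is
$\hat\rho_{loc} = (z_1^{\mathsf T} R_k^{+} z_2 - k\,c) / \sqrt{n_1 n_2}$
with cross-trait intercept $c$ (0 by default: the consortia analysed are
assumed non-overlapping; override via `overlap_term`). The rank policy
retains the smallest $k$ explaining 99% of the eigenvalue mass, capped
at 50; eigenvalues below $10^{-8}$ are always excluded, so padding $k$
past the numerical rank changes nothing.

Per-region p-values come from a seeded parametric simulation under
$\rho_{loc} = 0$ with the estimated local heritabilities (5000 draws by
default) rather than an analytic variance formula: the simulation is
directly checkable against an oracle and is exact for the two-sided
rank-based p at desk scale. Local correlation is reported only where
both local heritabilities are positive; otherwise the row carries a
reason code instead of an NaN cascade. The Bonferroni gate uses
`0.05 / (regions actually tested)`, and `p < 0.05` is labelled
suggestive, matching the convention of genome partitions of ~1703
LD-independent regions.

## Cross-phenotype meta-analysis

With per-trait z-scores aligned to a shared effect allele, weights
$w_k = \sqrt{N_k}$ ($\sqrt{N_{eff}}$, $N_{eff} = 4/(1/cases +
1/controls)$, for binary traits), and the trait-trait correlation $R$ of
the statistics,
$$S_{Hom} = \frac{(w^{\mathsf T} R^{-1} z)^2}{w^{\mathsf T} R^{-1} w}
  \sim \chi^2_1 .$$
$S_{Het}$ maximizes $S_{Hom}$ over the trait subsets obtained by
thresholding $|z_k| > \tau$, with the grid taken at the distinct
observed $|z|$ values (minus epsilon) plus 0 — exhaustive for the small
trait counts used here. Its null distribution is non-standard, so we
simulate `null_reps` draws of $z \sim MVN(0, R)$ and fit a gamma
distribution by maximum likelihood (`MASS::fitdistr`); p-values come from
the fitted upper tail and are therefore never exactly zero. The fit is
computed once per $(w, R)$ and reused across all SNPs of a scan. Tail
extrapolation beyond the simulated range is the known weak point of this
approximation (the original implementation shares it), which is why
exact reproduction of published extreme meta-analysis p-values is not
attempted; calibration at conventional levels is what the tests check.

$R$ is estimated as the Pearson correlation of z-scores over SNPs that
are null in **every** trait ($|z| < 1.96$), which isolates sample
overlap / relatedness from genetic signal. The truncation attenuates the
estimate (a true 0.5 shrinks to about 0.41); this conservative bias is
accepted because an inflated $R$ would cost power in $S_{Hom}$.

Screening keeps SNPs with meta-analysis $p < 5\times10^{-8}$ **and**
suggestive single-trait evidence ($p < 10^{-3}$ in at least one trait,
both finite); all boundaries exclusive. Candidates are clumped greedily
(sentinel = smallest p below `p1 = 5e-8`; members join with `p < 1e-5`,
within 500 kb and $r^2 \ge 0.2$ of the sentinel; ties broken by
chromosome and position; cross-region $r^2$ is 0 by construction).
Loci are classified 1–4: genome-wide significant in both traits
("known"), in exactly one ("single-trait-driven"), in LD
($r^2 > 0.2$) with a known index SNP ("LD-tagged"), else "novel".

## TWAS

For a gene with weight vector $w$ over its region's SNPs,
$Z = w^{\mathsf T} z / \sqrt{w^{\mathsf T} R w}$ — invariant to positive
rescaling of $w$, undefined (flagged, not an error) when the predicted
expression variance $w^{\mathsf T} R w$ is numerically zero. FDR control
is Benjamini–Hochberg **within each (trait, tissue) stratum**
(`stats::p.adjust`); no additional cross-tissue correction is applied,
matching the convention of per-tissue reporting. A gene is shared
between traits when it is FDR-significant in at least one tissue for
both; the output carries each trait's significant-tissue list and
z-score range. Weight training from individual-level expression data is
out of scope: weights are an input format, and the synthetic generator
provides sparse weight sets with a designated truly-associated gene set
for testing.

## Mendelian randomisation

All estimators work on harmonized `(bx, se_bx, by, se_by)` instrument
tables; estimates stay on the log-odds scale until report time.

* **IVW**: $\hat b = \sum b_x b_y/se_y^2 \big/ \sum b_x^2/se_y^2$. The
  default standard error is multiplicative random effects — the
  fixed-effect SE times $\max(1, \sqrt{Q/(K-1)})$ — because that is the
  convention of the toolchain this field uses; the fixed-effect variant
  is available and is the one whose test is exactly calibrated (the
  `max(1,·)` makes the random-effects test conservative, never
  anticonservative).
* **MR-Egger**: WLS of $b_y$ on $b_x$ with intercept after orienting all
  $b_x > 0$; the intercept estimates directional pleiotropy. SEs scale
  by $\max(1, \sqrt{RSS/(K-2)})$; p-values use a t reference with
  $K-2$ df (toolchain convention; the reference distribution is not
  dictated by the estimator itself).
* **Weighted median**: inverse-variance-weighted median of Wald ratios
  with linear interpolation at cumulative weight 0.5; SE from 1000
  seeded parametric bootstrap replicates.
* **Cochran's Q / funnel data** for heterogeneity; **I²_GX** for the
  NOME assumption, computed on the Egger-oriented $|b_x|$ scale, with
  SIMEX recommended below 0.9.
* **SIMEX-Egger**: noise inflation at $\lambda \in \{0.5, 1, 1.5, 2\}$,
  1000 simulations per grid point, quadratic extrapolation to
  $\lambda = -1$ (linear fallback if degenerate). The reported SE
  combines the simulation-batch jackknife (Monte-Carlo noise of the
  extrapolation) with the raw Egger sampling SE.
* **MR-PRESSO**: observed RSS built from leave-one-out IVW slopes; the
  global p is the smoothed simulation rank $(1 + \#\{sim \ge obs\})/(1 +
  n_{sim})$. Per-SNP outlier p-values use the raw simulation proportion,
  *not* the smoothed one: with the smoothed floor, Bonferroni at
  $\alpha = 0.05$ could never reject at moderate `n_sim`, silently
  disabling the outlier test. The corrected estimate is IVW on
  non-outliers. The distortion test is not implemented.
* **Steiger filtering**: per-SNP variance explained
  $r^2 = t^2/(t^2 + n - 2)$ on each side (effective n for binary
  traits); instruments explaining more outcome than exposure variance
  are removed and IVW re-run. SNPs without sample sizes are untestable
  and retained with a warning. The filter is idempotent.
* **Power**: $\Phi\big(\sqrt{n v (1-v) r^2}\,|\ln OR| -
  z_{1-\alpha/s}\big)$ for a binary outcome with case fraction $v$. The
  default is one-sided $\alpha = 0.05$ because only that convention
  reproduces the printed pairing of 80% power with OR 1.38 at
  $n = 113{,}238$, $v = 0.09$, $r^2 = 0.0062$ (the two-sided variant is
  a flag away); the closed form itself gives 78.7%.
* **Multivariable IVW**: WLS of $b_y$ on two exposure-effect columns
  without intercept; condition number above $10^8$ is treated as
  collinearity and refused.

`bidirectional_mr()` selects instruments at $p < 5\times10^{-8}$, clumps
them to independence at $r^2 < 0.01$ (the convention for instrument
selection, distinct from the 0.2 used for locus discovery), harmonizes,
Steiger-filters, and runs the battery in both directions. Directions
with fewer than three surviving instruments return a partial bundle with
a reason rather than failing.

# The synthetic-data generator

The generator is the package's ground truth and defines the study
conditions; its defaults are not tuned per test.

* **Effect model**: per-SNP true effects are bivariate normal on the
  standardized-genotype scale, $\mathrm{Var} = h^2_t/m$,
  $\mathrm{Cov} = r_g \sqrt{h^2_1 h^2_2}/m$ — the uniform (GCTA-style)
  architecture that LD-score regression itself assumes. Defaults:
  $m = 10{,}000$, $n = 50{,}000$ per trait, $h^2 = 0.3$,
  $r_g = 0.31$ — the headline regime of the diabetes–PCOS analyses.
* **Observed statistics**: per region,
  $z_t = \sqrt{n_t}\, R \beta_t + \varepsilon_t$ with
  $\varepsilon \sim MVN(0, R)$ and cross-trait noise correlation
  $\rho_{pheno}\, n_{overlap}/\sqrt{n_1 n_2}$. Betas are back-filled as
  $z/\sqrt n$, SEs as $1/\sqrt n$: simulation works on the standardized
  scale throughout, sidestepping the mixed units (log-OR, mmol/l, %) of
  real trait sets. Case-control traits enter through
  $N_{eff} = 4/(1/cases + 1/controls)$.
* **LD**: block-diagonal AR(1). A single correlation value makes all LD
  scores nearly equal, which leaves the LDSC intercept nearly
  unidentified, so the default panels mix block strengths
  $\rho \in \{0.1, 0.4, 0.7, 0.9\}$ (LD scores ranging ~1–8.4), a crude
  but serviceable stand-in for the heterogeneous LD of real genomes.
  Regions coincide with block boundaries, making the partition exactly
  LD-independent.
* **MR instruments**: $b_x \sim N(0.08, 0.02^2)$ (strong, as index SNPs
  are), $b_y = \beta_{causal} b_x + \alpha_j$,
  $\alpha_j \sim N(\mu_{pleio}, \sigma_{pleio}^2)$ independent of $b_x$
  (InSIDE holds by construction); optional gross outliers add ±0.3.
  Measurement noise is $N(0, se^2)$ with $se = 1/\sqrt n$; `noise =
  FALSE` gives error-free effects for exactness tests.
* **TWAS**: sparse standard-normal weight vectors per gene over one
  region's SNPs; designated causal genes can spike the trait z-vector
  along $\lambda R w / \sqrt{w^{\mathsf T} R w}$ so the expected TWAS
  z-score is exactly $\lambda$.

All generators are pure functions of (parameters, seed) and reproduce
bit-identically under the same seed.

**What the simulations do not emulate**: MAF- or LD-dependent genetic
architecture, population stratification (the regression intercepts are
assumed to absorb it), cross-region LD leakage, imputation-quality
variation, and real allele-frequency spectra. Passing tests therefore
demonstrate correctness of the estimators under their own model
assumptions, not robustness to every failure mode of real GWAS data.

# Problem sizes, tolerances and degenerate inputs

Tests and the acceptance script use $m = 10{,}000$ SNPs for
genetic-correlation recovery (single-replicate SE ≈ 0.06), 2000-replicate
calibration checks with 95% binomial bands (±1 percentage point slack for
Monte-Carlo error of the shared nulls), 42–231 instruments for MR
recovery mirroring the real instrument counts, and 5000-draw parametric
nulls per region for local covariance. These sizes were chosen so each
stage's sampling error is small relative to the effects being recovered
while the whole suite runs in minutes on one CPU.

Degenerate inputs are handled without exceptions wherever a flagged
result is more useful: nonpositive heritability (flagged `NA` $r_g$),
zero expression variance (flagged TWAS row), $b_x = 0$ (flagged Wald
ratio), fewer than 3 (Egger/median) or 4 (PRESSO) instruments (reason
codes), empty clumping input (empty list). Hard errors are reserved for
contract violations: missing columns, zero surviving rows, singular
trait correlation, collinear exposures, invalid p-values or correlation
parameters.

# Known limitations

* The gamma-tail approximation for $S_{Het}$ is accurate to roughly an
  order of magnitude in the extreme tail; published meta-analysis
  p-values at $10^{-20}$ and beyond are not reproducible by any
  simulation-based null at desk scale.
* The LDSC intercept estimate carries a small positive finite-sample
  bias below a few thousand SNPs (estimated weights), and its SE grows
  quickly as the LD-score spread narrows.
* The null-SNP trait-correlation estimator is attenuated by its own
  truncation; for traits with very strong overlap the $S_{Hom}$ test is
  accordingly slightly conservative.
* Local p-values are Monte-Carlo: their resolution is bounded by
  `1/(n_null + 1)` per region.
* No one-sample MR, no LD-aware (correlated-instrument) IVW, no
  liftover, no VCF input, no annotation of clumped ranges: these are
  outside the package's scope.
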