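# crosstraitr

Genome-wide cross-trait analysis from GWAS summary statistics, for
statistical geneticists and epidemiologists who want to dissect the
shared genetic basis of two complex traits — the motivating case being
type 2 diabetes / glycaemic traits and polycystic ovary syndrome (PCOS) —
into horizontal pleiotropy and causation, using summary-level data only.

The package implements five loosely coupled stages:

| Stage | Core quantity | Functions |
|---|---|---|
| Overall genetic correlation | LD-score regression: slope of χ²ⱼ on n·ℓⱼ/m gives h²; slope of z₁ⱼz₂ⱼ on √(n₁n₂)·ℓⱼ/m gives the genetic covariance ρ_g; r_g = ρ_g/√(h²₁h²₂) with block-jackknife SE | `estimate_h2`, `estimate_rg` |
| Local genetic correlation | per-region ĥ²_loc = (zᵀR_k⁺z − k)/(n − k) and ρ̂_loc = (z₁ᵀR_k⁺z₂ − k·c)/√(n₁n₂) via truncated LD eigendecomposition; simulation p-values | `local_h2`, `local_gencov`, `local_correlation_scan` |
| Cross-phenotype meta-analysis | S_Hom = (wᵀR⁻¹z)²/(wᵀR⁻¹w) ~ χ²₁ and S_Het = max over \|z\|-threshold trait subsets (gamma-fitted Monte-Carlo null); screening, greedy clumping, 4-category locus classification | `s_hom`, `s_het`, `screen_pleiotropic`, `clump`, `classify_locus`, `cpassoc_scan` |
| TWAS | Z = wᵀz/√(wᵀRw) from expression weights and GWAS z-scores; per-tissue BH-FDR; cross-trait gene intersection | `twas_z`, `bh_fdr`, `twas_scan`, `intersect_significant` |
| Bidirectional MR | IVW, MR-Egger (+SIMEX), weighted median, Cochran's Q, I²_GX, MR-PRESSO, Steiger filtering, leave-one-out, F statistics, closed-form power | `mr_battery`, `bidirectional_mr`, `mr_power`, ... |

A synthetic-data module (`sim_truth`, `make_ld_panel`, `simulate_pair`,
`simulate_instruments`, `simulate_twas_weights`) generates coupled
summary statistics, LD panels, instrument sets and expression weights
with known ground truth, so the whole pipeline is testable without any
external download. `run_pipeline()` chains everything from one config.

## Worked example

Estimate the genetic correlation of a simulated trait pair generated at
the published diabetes–PCOS regime (m = 10,000 SNPs, n = 50,000 per
trait, h² = 0.3, true r_g = 0.31), then run the MR battery on a
231-instrument set with a true causal odds ratio of 1.15 on a binary
outcome of 10,074 cases / 103,164 controls:

```r
library(crosstraitr)

panel <- make_ld_panel(ld_block_spec(500, 20, c(0.1, 0.4, 0.7, 0.9)))
pair  <- simulate_pair(sim_truth(rg_true = 0.31), panel, seed = 42)
estimate_rg(pair$ss1, pair$ss2, panel, n_blocks = 100)
#> rg = 0.3492 (SE 0.0568), p = 7.63e-10  [gencov 0.0985, h2 0.2771 / 0.2871, 9888 SNPs]

iv <- simulate_instruments(
  sim_truth(causal_b = log(1.15), n1 = 300000,
            n_case2 = 10074, n_control2 = 103164),
  k = 231, seed = 42)
mr_battery(iv, seed = 42)
#> MR bundle: K = 231 instruments (mean F 2001.6)
#>   IVW: 0.1358 (SE 0.0042, p 1.86e-228)  OR 1.145 [1.136, 1.155]
```

The r_g estimate recovers the generating value 0.31 within its jackknife
SE and is Bonferroni-significant at the 6-trait-pair gate (p < 0.05/6).
The IVW odds ratio 1.145 recovers the generating OR 1.15; in the same
bundle MR-Egger gives OR 1.145 [1.107, 1.186] with a null pleiotropy
intercept (p = 1.00), the weighted median 1.150 [1.136, 1.164],
Cochran's Q = 230.3 on 230 df (p = 0.48, no heterogeneity), the
MR-PRESSO global test p = 0.474, and Steiger filtering removes no
instrument — the full sensitivity battery agrees with the primary
estimate, as it should on clean data.

The closed-form power calculation for detecting OR 1.38 on an outcome of
n = 113,238 (9% cases) with instruments explaining 0.62% of exposure
variance returns

```r
mr_power(n = 113238, v = 0.09, r2 = 0.0062, odds_ratio = 1.38)
#> [1] 0.7874096
```

i.e. ~80% power, one-sided α = 0.05.

A bundled table of published pleiotropic SNPs for the five diabetes- and
glycaemic-trait pairs with PCOS (`published_pleiotropic_snps()`) feeds
the screening utilities: all 19 rows pass the dual-significance rule
(p_CPASSOC < 5×10⁻⁸ and single-trait p < 10⁻³), comprising 16 distinct
independent pleiotropic SNPs of which 7 are flagged novel.

## Documentation

The methods vignette (`vignettes/cross-trait-analysis.Rmd`) describes
the models, estimator choices, the synthetic generator's assumptions and
what passing tests do and do not establish about real data; function
documentation is in the roxygen comments under `R/`.
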