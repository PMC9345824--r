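# Two-sample MR estimators and the sensitivity battery.

iv_exact <- function(k = 10, b = 0.25, seed = 1) {
  simulate_instruments(sim_truth(causal_b = b), k = k, seed = seed,
                       noise = FALSE)
}

test_that("Wald ratio and its delta-method SE are exact", {
  expect_equal(wald_ratio(0.1, 0.02, 0.2, 0.05)$estimate, 2)
  expect_equal(wald_ratio(0.1, 0.02, 0, 0.05)$estimate, 0)
  expect_equal(wald_ratio(0.1, 0.02, 0.2, 0.05)$se, 0.5)
  expect_true(is.na(wald_ratio(0, 0.02, 0.2, 0.05)$estimate))
})

test_that("IVW reproduces exact slopes and falls back to Wald at K = 1", {
  iv <- iv_exact(b = 0.25)
  f <- ivw(iv)
  expect_equal(f$estimate, 0.25, tolerance = 1e-12)
  expect_equal(f$q, 0, tolerance = 1e-9)
  # identical SNPs: IVW equals the single Wald ratio
  iv1 <- mr_instruments("a", 0.1, 0.01, 0.05, 0.02)
  iv_rep <- iv1[rep(1, 5), ]
  expect_equal(ivw(iv_rep)$estimate, 0.5)
  expect_warning(f1 <- ivw(iv1), "Wald")
  expect_equal(f1$estimate, 0.5)
  # fixed-effect SE never exceeds the multiplicative-random SE
  ivn <- simulate_instruments(sim_truth(causal_b = 0.1, pleio_sd = 0.02),
                              k = 30, seed = 2)
  expect_lte(ivw(ivn, "fixed")$se, ivw(ivn)$se)
})

test_that("IVW recovers the published-scale causal effects within 2 SE", {
  # OR 1.15 regime: large binary exposure/outcome GWAS, 231 instruments
  tr1 <- sim_truth(causal_b = log(1.15), n1 = 300000,
                   n_case2 = 10074, n_control2 = 103164)
  iv1 <- simulate_instruments(tr1, k = 231, seed = 3)
  f1 <- ivw(iv1)
  expect_lt(abs(f1$estimate - log(1.15)), 2 * f1$se)
  # OR 2.85 regime: 42 instruments, quantitative exposure
  tr2 <- sim_truth(causal_b = log(2.85), n1 = 200000,
                   n_case2 = 10074, n_control2 = 103164)
  iv2 <- simulate_instruments(tr2, k = 42, seed = 4)
  f2 <- ivw(iv2)
  expect_lt(abs(f2$estimate - log(2.85)), 2 * f2$se)
})

test_that("MR-Egger recovers slope and planted directional pleiotropy", {
  iv <- iv_exact(b = 0.3)
  e <- mr_egger(iv)
  expect_equal(e$estimate, 0.3, tolerance = 1e-9)
  expect_equal(e$intercept, 0, tolerance = 1e-9)
  # directional pleiotropy alpha = 0.02 under InSIDE
  tr <- sim_truth(causal_b = 0.2, pleio_mean = 0.02, pleio_sd = 0.005)
  ivp <- simulate_instruments(tr, k = 100, seed = 5)
  ep <- mr_egger(ivp)
  expect_lt(abs(ep$intercept - 0.02), 2 * ep$intercept_se)
  expect_lt(abs(ep$estimate - 0.2), 2 * ep$se)
  # orientation invariance: flipping any SNP's signs changes nothing
  iv_fl <- ivp
  iv_fl$bx[3] <- -iv_fl$bx[3]
  iv_fl$by[3] <- -iv_fl$by[3]
  expect_equal(mr_egger(iv_fl)$estimate, ep$estimate, tolerance = 1e-12)
  expect_equal(mr_egger(iv_fl)$intercept, ep$intercept, tolerance = 1e-12)
  expect_equal(mr_egger(iv_exact(k = 3))$k, 3)
  expect_equal(mr_egger(iv_exact(k = 4)[1:2, ])$reason,
               "fewer_than_3_instruments")
})

test_that("weighted median matches the simple median with equal weights", {
  # 5 ratios with equal precision: estimate equals the middle ratio
  bx <- rep(0.1, 5)
  by <- c(0.1, 0.2, 0.3, 0.4, 0.5) * 0.1
  iv <- mr_instruments(paste0("s", 1:5), bx, 0.01, by, 0.02)
  wm <- weighted_median(iv, n_boot = 200, seed = 6)
  expect_equal(wm$estimate, 0.3, tolerance = 1e-9)
  # all ratios equal: that value with a small bootstrap SE
  iv_same <- mr_instruments(paste0("s", 1:5), bx, 0.001, rep(0.03, 5), 0.001)
  wm_same <- weighted_median(iv_same, n_boot = 200, seed = 6)
  expect_equal(wm_same$estimate, 0.3, tolerance = 1e-9)
  expect_lt(wm_same$se, 0.05)
})

test_that("weighted median resists 40% invalid instruments", {
  set.seed(7)
  k <- 50
  bx <- rnorm(k, 0.1, 0.01)
  by <- 0.2 * bx
  by[1:20] <- by[1:20] + 5 * bx[1:20]   # 40% gross outliers
  iv <- mr_instruments(paste0("s", 1:k), bx, 0.002, by, 0.002)
  wm <- weighted_median(iv, n_boot = 500, seed = 8)
  expect_lt(abs(wm$estimate - 0.2), 2 * wm$se + 0.02)
  expect_lt(abs(wm$estimate - 0.2), 0.05)
})

test_that("Cochran's Q is zero on proportional data and flags the outlier", {
  iv <- iv_exact(b = 0.25)
  q0 <- cochran_q(iv, ivw(iv)$estimate)
  expect_equal(q0$q, 0, tolerance = 1e-9)
  expect_equal(q0$p, 1)
  iv_out <- iv
  iv_out$by[4] <- iv_out$by[4] + 0.2
  q1 <- cochran_q(iv_out, ivw(iv_out)$estimate)
  expect_gt(q1$q, q0$q)
  expect_equal(names(which.max(q1$contributions)), "iv4")
  # calibration: Q/df near 1 on clean noisy replicates
  qdf <- vapply(1:50, function(s) {
    ivs <- simulate_instruments(sim_truth(causal_b = 0.1), k = 30, seed = s)
    f <- ivw(ivs)
    f$q / f$q_df
  }, numeric(1))
  expect_equal(mean(qdf), 1, tolerance = 0.15)
})

test_that("I2_GX detects exposure measurement-error dilution", {
  iv_strong <- mr_instruments(paste0("s", 1:10), seq(0.05, 0.2, length.out = 10),
                              1e-5, 0.02, 0.01)
  expect_gt(i2_gx(iv_strong)$i2, 0.99)
  iv_flat <- mr_instruments(paste0("s", 1:10), rep(0.1, 10), 0.01, 0.02, 0.01)
  expect_equal(i2_gx(iv_flat)$i2, 0)
  # weak instruments (large se_bx) push I2 below 0.9 and flag SIMEX
  tr <- sim_truth(n1 = 800)   # tiny exposure GWAS -> se_bx = 0.035
  iv_weak <- simulate_instruments(tr, k = 30, seed = 9)
  res <- i2_gx(iv_weak)
  expect_lt(res$i2, 0.9)
  expect_true(res$simex_recommended)
})

test_that("SIMEX moves the diluted Egger slope back toward the truth", {
  tr <- sim_truth(causal_b = 0.25, n1 = 2000)  # heavy dilution
  closer <- vapply(1:10, function(s) {
    iv <- simulate_instruments(tr, k = 60, seed = s)
    raw <- mr_egger(iv)$estimate
    cor <- simex_egger(iv, n_sim = 200, seed = 1000 + s)$estimate
    abs(cor - 0.25) < abs(raw - 0.25)
  }, logical(1))
  expect_gte(mean(closer), 0.9)
  # no exposure noise: corrected slope equals the raw slope
  iv0 <- iv_exact(b = 0.2)
  iv0$se_bx <- 0
  expect_equal(simex_egger(iv0)$estimate, mr_egger(iv0)$estimate)
  expect_error(simex_egger(iv_exact(), lambda_grid = 0), "lambda_grid")
})

test_that("MR-PRESSO flags planted outliers and improves the estimate", {
  improved <- vapply(1:10, function(s) {
    tr <- sim_truth(causal_b = 0.2, n_outliers = 2)
    iv <- simulate_instruments(tr, k = 40, seed = s)
    pr <- mr_presso(iv, n_sim = 500, seed = 2000 + s)
    both_found <- all(c("iv1", "iv2") %in% pr$outliers)
    est <- if (!is.null(pr$corrected)) pr$corrected$estimate else pr$raw$estimate
    c(both_found, abs(est - 0.2) <= abs(pr$raw$estimate - 0.2))
  }, logical(2))
  expect_gte(mean(improved[1, ]), 0.9)
  expect_gte(mean(improved[2, ]), 0.9)
  expect_equal(mr_presso(iv_exact(k = 3))$reason, "fewer_than_4_instruments")
  expect_error(mr_presso(iv_exact(), n_sim = 0), "n_sim")
})

test_that("Steiger filtering keeps forward and removes reverse instruments", {
  n <- 50000
  iv <- mr_instruments(c("f", "r"), bx = c(10, 2) / sqrt(n), se_bx = 1 / sqrt(n),
                       by = c(2, 10) / sqrt(n), se_by = 1 / sqrt(n),
                       n_exposure = n, n_outcome = n)
  st <- steiger_filter(iv)
  expect_equal(st$retained$snp, "f")
  expect_equal(st$removed, "r")
  # idempotence
  st2 <- steiger_filter(st$retained)
  expect_equal(st2$retained$snp, st$retained$snp)
  expect_length(st2$removed, 0)
  # missing sample sizes: retained with a warning
  iv_na <- mr_instruments("u", 0.1, 0.01, 0.2, 0.01)
  expect_warning(st3 <- steiger_filter(iv_na), "without sample sizes")
  expect_equal(st3$retained$snp, "u")
})

test_that("Steiger removes most instruments under reverse causation", {
  # trait 2 -> trait 1: instruments chosen on trait 1's induced signal
  removed_majority <- vapply(1:10, function(s) {
    k <- 30
    iv_fwd <- simulate_instruments(sim_truth(causal_b = 0.3, n1 = 100000,
                                             n2 = 30000), k = k, seed = s)
    # swap roles: 'exposure' is the downstream trait (attenuated effects,
    # smaller GWAS), outcome is the true upstream trait
    iv_rev <- mr_instruments(iv_fwd$snp, bx = 0.3 * iv_fwd$bx,
                             se_bx = 1 / sqrt(30000), by = iv_fwd$bx,
                             se_by = iv_fwd$se_bx, n_exposure = 30000,
                             n_outcome = 100000)
    length(steiger_filter(iv_rev)$removed) > k / 2
  }, logical(1))
  expect_gte(mean(removed_majority), 0.9)
})

test_that("leave-one-out isolates a dominant outlier", {
  iv <- simulate_instruments(sim_truth(causal_b = 0.2), k = 20, seed = 10)
  iv$by[5] <- iv$by[5] + 0.5
  lo <- leave_one_out(iv)
  expect_equal(nrow(lo), 21)
  full <- lo$estimate[lo$snp_left_out == "(all)"]
  dev <- abs(lo$estimate[lo$snp_left_out != "(all)"] - full)
  expect_equal(which.max(dev), 5L)
  # homogeneous instruments: every LOO estimate within 2 SE of the full one
  iv_h <- simulate_instruments(sim_truth(causal_b = 0.2), k = 20, seed = 11)
  lo_h <- leave_one_out(iv_h)
  full_h <- lo_h[lo_h$snp_left_out == "(all)", ]
  expect_true(all(abs(lo_h$estimate - full_h$estimate) <= 2 * full_h$se))
})

test_that("instrument strength summarises F statistics", {
  iv <- mr_instruments("a", 0.1, 0.02, 0.2, 0.05)
  expect_equal(unname(instrument_strength(iv)$f), 25)
  # genome-wide significant instruments are all strong: |z| > 5.45 -> F > 29.7
  tr <- sim_truth(n1 = 200000)
  ivs <- simulate_instruments(tr, k = 50, seed = 12)
  zx <- abs(ivs$bx / ivs$se_bx)
  ivs <- ivs[zx > 5.45, ]
  expect_true(all(instrument_strength(ivs)$f > 29.7))
  empty <- instrument_strength(ivs[0, ])
  expect_length(empty$f, 0)
  expect_true(is.na(empty$mean_f))
})

test_that("MR power matches the closed form and the printed 80% claim", {
  # null OR: power equals the alpha level (one-sided)
  expect_equal(mr_power(50000, 0.1, 0.01, 1, alpha = 0.05), 0.05,
               tolerance = 1e-12)
  p80 <- mr_power(n = 113238, v = 0.09, r2 = 0.0062, odds_ratio = 1.38,
                  alpha = 0.05, sided = "one")
  expect_gt(p80, 0.78)
  expect_lt(p80, 0.80)
  # monotone in n and in |ln OR|
  expect_gt(mr_power(2e5, 0.09, 0.0062, 1.38), p80)
  expect_gt(mr_power(113238, 0.09, 0.0062, 1.5), p80)
  expect_gt(p80, mr_power(113238, 0.09, 0.0062, 1.38, sided = "two"))
  expect_error(mr_power(1000, 0.1, 0, 1.5), "r2")
})

test_that("multivariable IVW reduces to univariable with a null column", {
  iv <- simulate_instruments(sim_truth(causal_b = 0.2), k = 30, seed = 13)
  ivm <- data.frame(bx1 = iv$bx, bx2 = 0, by = iv$by, se_by = iv$se_by)
  # an all-zero column is collinearity-degenerate; jitter minimally instead
  ivm$bx2 <- rnorm(30, 0, 1e-4)
  fit <- mvmr_ivw(ivm)
  expect_equal(fit$estimate[1], ivw(iv)$estimate, tolerance = 1e-2)
  # joint recovery of two direct effects
  set.seed(14)
  k <- 50
  bx1 <- rnorm(k, 0.1, 0.03); bx2 <- rnorm(k, 0.08, 0.03)
  by <- 0.1 * bx1 + 0.2 * bx2 + rnorm(k, 0, 0.004)
  fit2 <- mvmr_ivw(data.frame(bx1 = bx1, bx2 = bx2, by = by, se_by = 0.004))
  expect_lt(abs(fit2$estimate[1] - 0.1), 2 * fit2$se[1])
  expect_lt(abs(fit2$estimate[2] - 0.2), 2 * fit2$se[2])
  # K = 3 with 2 exposures is computable (df = 1)
  fit3 <- mvmr_ivw(data.frame(bx1 = bx1[1:3], bx2 = bx2[1:3], by = by[1:3],
                              se_by = 0.004))
  expect_equal(nrow(fit3), 2)
  # collinear exposures error
  expect_error(mvmr_ivw(data.frame(bx1 = bx1, bx2 = bx1, by = by,
                                   se_by = 0.004)), "collinear")
})

test_that("estimators are equivariant in the outcome scale", {
  iv <- simulate_instruments(sim_truth(causal_b = 0.2, pleio_sd = 0.01),
                             k = 25, seed = 15)
  iv_c <- iv
  cst <- 3.7
  iv_c$by <- cst * iv$by
  iv_c$se_by <- cst * iv$se_by
  expect_equal(ivw(iv_c)$estimate, cst * ivw(iv)$estimate, tolerance = 1e-12)
  expect_equal(ivw(iv_c)$se, cst * ivw(iv)$se, tolerance = 1e-12)
  expect_equal(mr_egger(iv_c)$estimate, cst * mr_egger(iv)$estimate,
               tolerance = 1e-12)
  expect_equal(weighted_median(iv_c, 200, 1)$estimate,
               cst * weighted_median(iv, 200, 1)$estimate, tolerance = 1e-12)
})

test_that("Egger with intercept constrained to zero equals IVW", {
  iv <- simulate_instruments(sim_truth(causal_b = 0.2), k = 20, seed = 16)
  # no-intercept weighted regression of by on bx IS the IVW estimator
  w <- 1 / iv$se_by^2
  slope <- sum(w * iv$bx * iv$by) / sum(w * iv$bx^2)
  expect_equal(slope, ivw(iv)$estimate, tolerance = 1e-12)
})

test_that("bidirectional MR separates cause from consequence", {
  panel <- rg_panel()
  # trait 1 causes trait 2: simulate coupled GWAS where trait 2 inherits
  # trait 1's signal scaled by the causal effect, plus its own noise
  b_causal <- 0.4
  truth <- sim_truth(h2_1 = 0.5, h2_2 = 0, rg_true = 0, n1 = 200000,
                     n2 = 50000)
  pair <- simulate_pair(truth, panel, seed = 17)
  z1 <- pair$ss1$beta / pair$ss1$se
  z2 <- pair$ss2$beta / pair$ss2$se +
    b_causal * sqrt(50000 / 200000) * z1   # beta2 = b * beta1
  ss2 <- pair$ss2
  ss2$beta <- z2 * ss2$se
  ss2$p <- 2 * pnorm(-abs(z2))
  res <- suppressWarnings(bidirectional_mr(pair$ss1, ss2, panel, seed = 18))
  expect_gte(res$forward$k, 3)
  f <- res$forward$ivw
  expect_lt(abs(f$estimate - b_causal), 3 * f$se)
  # reverse direction: few/weak instruments survive Steiger, and if an
  # estimate exists it is near zero
  if (!is.null(res$reverse$ivw)) {
    expect_gt(res$reverse$ivw$p, 0.05 / 6)
  } else {
    expect_match(res$reverse$reason, "instruments")
  }
})

test_that("IVW fixed-effect test is calibrated at alpha = 0.05 under the null", {
  reps <- 2000
  set.seed(19)
  rej <- vapply(seq_len(reps), function(i) {
    k <- 30
    bx <- rnorm(k, 0.08, 0.02)
    by <- rnorm(k, 0, 0.01)
    iv <- mr_instruments(paste0("s", 1:k), bx, 0.004, by, 0.01)
    c(fixed = ivw(iv, "fixed")$p < 0.05, mre = ivw(iv)$p < 0.05)
  }, logical(2))
  band <- 1.96 * sqrt(0.05 * 0.95 / reps)
  expect_gt(mean(rej["fixed", ]), 0.05 - band - 0.005)
  expect_lt(mean(rej["fixed", ]), 0.05 + band + 0.005)
  # the multiplicative-random-effects default never rejects more often
  expect_lte(mean(rej["mre", ]), mean(rej["fixed", ]))
})

test_that("MR-PRESSO global test is calibrated under the clean null", {
  reps <- 400
  set.seed(20)
  pvals <- vapply(seq_len(reps), function(i) {
    k <- 20
    bx <- rnorm(k, 0.08, 0.02)
    by <- 0.1 * bx + rnorm(k, 0, 0.01)
    iv <- mr_instruments(paste0("s", 1:k), bx, 0.004, by, 0.01)
    mr_presso(iv, n_sim = 300, seed = i)$global_p
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  band <- 1.96 * sqrt(0.05 * 0.95 / reps)
  expect_gt(rate, 0.05 - band - 0.02)
  expect_lt(rate, 0.05 + band + 0.02)
})
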