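#' Two-sample Mendelian randomisation estimators and sensitivity battery
#'
#' All estimators consume an `mr_instruments` table of harmonized
#' per-SNP effect pairs: `bx, se_bx` on the exposure and `by, se_by` on
#' the outcome. Estimates live on the regression scale (log-odds when the
#' outcome is binary) and are exponentiated only at report time.
#'
#' @name mr_suite
NULL

#' Construct an MR instrument table
#'
#' @param snp rsIDs.
#' @param bx,se_bx instrument-exposure effect and SE.
#' @param by,se_by instrument-outcome effect and SE.
#' @param eaf optional effect-allele frequency.
#' @param n_exposure,n_outcome optional sample sizes (needed for Steiger).
#' @param v_case_out optional case fraction of a binary outcome.
#' @param palindromic optional logical flag per SNP.
#' @return data frame of class `mr_instruments`.
#' @export
mr_instruments <- function(snp, bx, se_bx, by, se_by, eaf = NA_real_,
                           n_exposure = NA_real_, n_outcome = NA_real_,
                           v_case_out = NA_real_, palindromic = FALSE) {
  if (any(se_bx <= 0) || any(se_by <= 0)) stopf("standard errors must be positive")
  out <- data.frame(snp = as.character(snp), bx = bx, se_bx = se_bx,
                    by = by, se_by = se_by, eaf = eaf,
                    n_exposure = n_exposure, n_outcome = n_outcome,
                    v_case_out = v_case_out, palindromic = palindromic,
                    stringsAsFactors = FALSE)
  class(out) <- c("mr_instruments", "data.frame")
  out
}

ci95 <- function(est, se) c(lower = est - 1.96 * se, upper = est + 1.96 * se)

#' Wald ratio for a single instrument
#'
#' @param bx,se_bx exposure effect and SE.
#' @param by,se_by outcome effect and SE.
#' @return list with `estimate`, `se` (first-order delta method), `p`;
#'   `NA` with a reason when `bx = 0`.
#' @export
wald_ratio <- function(bx, se_bx, by, se_by) {
  if (bx == 0) {
    return(list(estimate = NA_real_, se = NA_real_, p = NA_real_,
                reason = "zero_exposure_effect"))
  }
  est <- by / bx
  se <- se_by / abs(bx)
  list(estimate = est, se = se, p = 2 * stats::pnorm(-abs(est / se)), reason = "")
}

#' Inverse-variance-weighted MR estimate
#'
#' `b = sum(bx*by/se_by^2) / sum(bx^2/se_by^2)`; the fixed-effect SE is
#' `1/sqrt(sum(bx^2/se_by^2))` and the multiplicative-random-effects SE
#' (the default) multiplies it by `max(1, sqrt(Q/(K-1)))`.
#'
#' @param iv an [mr_instruments] table.
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return list with `estimate, se, ci, p, q, q_df, q_p, k, model`.
#' @export
ivw <- function(iv, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  K <- nrow(iv)
  if (K < 2) {
    warnf("IVW with %d instrument(s): falling back to the Wald ratio", K)
    wr <- wald_ratio(iv$bx, iv$se_bx, iv$by, iv$se_by)
    return(list(estimate = wr$estimate, se = wr$se,
                ci = ci95(wr$estimate, wr$se), p = wr$p,
                q = NA_real_, q_df = NA_integer_, q_p = NA_real_,
                k = K, model = "wald_ratio"))
  }
  wts <- 1 / iv$se_by^2
  denom <- sum(iv$bx^2 * wts)
  est <- sum(iv$bx * iv$by * wts) / denom
  se_fixed <- 1 / sqrt(denom)
  q <- sum((iv$by - est * iv$bx)^2 * wts)
  scale <- if (effects_model == "multiplicative_random") max(1, sqrt(q / (K - 1))) else 1
  se <- se_fixed * scale
  list(estimate = est, se = se, ci = ci95(est, se),
       p = 2 * stats::pnorm(-abs(est / se)),
       q = q, q_df = K - 1L, q_p = stats::pchisq(q, K - 1, lower.tail = FALSE),
       k = K, model = effects_model)
}

#' MR-Egger regression
#'
#' Weighted least squares of `by` on `bx` with a free intercept (weights
#' `1/se_by^2`), after orienting every SNP so `bx > 0`. The intercept
#' estimates directional pleiotropy; SEs are scaled by
#' `max(1, sqrt(RSS/(K-2)))` and p-values use a t reference with K-2 df.
#'
#' @param iv an [mr_instruments] table with K >= 3.
#' @return list with slope/intercept estimates, SEs, CIs and p-values.
#' @export
mr_egger <- function(iv) {
  K <- nrow(iv)
  if (K < 3) {
    return(list(estimate = NA_real_, se = NA_real_, p = NA_real_,
                intercept = NA_real_, intercept_se = NA_real_,
                intercept_p = NA_real_, k = K, reason = "fewer_than_3_instruments"))
  }
  flip <- sign(iv$bx)
  flip[flip == 0] <- 1
  bx <- iv$bx * flip
  by <- iv$by * flip
  f <- wls_fit(cbind(bx = bx, icept = 1), by, 1 / iv$se_by^2)
  cf <- unname(f$coef)
  se <- unname(sqrt(diag(f$vcov)))
  p <- 2 * stats::pt(-abs(cf / se), df = K - 2)
  list(estimate = cf[1], se = se[1], ci = ci95(cf[1], se[1]), p = p[1],
       intercept = cf[2], intercept_se = se[2],
       intercept_ci = ci95(cf[2], se[2]), intercept_p = p[2],
       k = K, sigma_scale = f$sigma_scale, reason = "")
}

#' Weighted-median MR estimate
#'
#' Per-SNP Wald ratios are sorted; weights proportional to the inverse
#' variance of each ratio are accumulated and the estimate is the linear
#' interpolation of the sorted ratios at cumulative weight 0.5. The SE is
#' the standard deviation of `n_boot` parametric-bootstrap re-estimates
#' (resampling bx and by from their sampling normals).
#'
#' @param iv an [mr_instruments] table with K >= 3.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return list with `estimate, se, ci, p`.
#' @export
weighted_median <- function(iv, n_boot = 1000L, seed = 1L) {
  K <- nrow(iv)
  if (K < 3) stopf("weighted median needs >= 3 instruments")
  wm <- function(bx, by) {
    ratio <- by / bx
    w <- (bx / iv$se_by)^2         # 1 / var(ratio), first order
    o <- order(ratio)
    ratio <- ratio[o]; w <- w[o]
    cw <- cumsum(w) - 0.5 * w
    cw <- cw / sum(w)
    stats::approx(cw, ratio, xout = 0.5, rule = 2)$y
  }
  est <- wm(iv$bx, iv$by)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      wm(stats::rnorm(K, iv$bx, iv$se_bx), stats::rnorm(K, iv$by, iv$se_by))
    }, numeric(1))
  })
  se <- stats::sd(boots)
  list(estimate = est, se = se, ci = ci95(est, se),
       p = 2 * stats::pnorm(-abs(est / se)))
}

#' Cochran's Q heterogeneity statistic
#'
#' @param iv an [mr_instruments] table.
#' @param b_ref reference causal estimate (e.g. the IVW estimate).
#' @return list with `q`, per-SNP contributions, `df`, `p`.
#' @export
cochran_q <- function(iv, b_ref) {
  contrib <- (iv$by - b_ref * iv$bx)^2 / iv$se_by^2
  q <- sum(contrib)
  df <- nrow(iv) - 1L
  list(q = q, contributions = stats::setNames(contrib, iv$snp), df = df,
       p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Funnel-plot data: per-SNP ratio estimates against precision
#'
#' @param iv an [mr_instruments] table.
#' @return data frame `snp, ratio, se_ratio, precision`.
#' @export
funnel_data <- function(iv) {
  se_ratio <- iv$se_by / abs(iv$bx)
  data.frame(snp = iv$snp, ratio = iv$by / iv$bx, se_ratio = se_ratio,
             precision = 1 / se_ratio, stringsAsFactors = FALSE)
}

#' I-squared statistic for the NOME assumption on exposure effects
#'
#' Measures regression dilution of the MR-Egger slope: values below ~0.9
#' indicate that SIMEX correction is advisable.
#'
#' @param iv an [mr_instruments] table.
#' @return list with `i2`, `q_gx`, and `simex_recommended` (i2 < 0.9).
#' @export
i2_gx <- function(iv) {
  w <- 1 / iv$se_bx^2
  # orient as Egger does so dispersion is measured on the analysis scale
  bx <- abs(iv$bx)
  bbar <- sum(w * bx) / sum(w)
  q_gx <- sum(w * (bx - bbar)^2)
  i2 <- max(0, (q_gx - (nrow(iv) - 1)) / q_gx)
  list(i2 = i2, q_gx = q_gx, simex_recommended = i2 < 0.9)
}

#' SIMEX-corrected MR-Egger slope
#'
#' For each lambda in the grid, `n_sim` perturbed datasets add
#' `N(0, lambda * se_bx^2)` noise to bx and the Egger slope is refit and
#' averaged; a quadratic in lambda (including the lambda = 0 raw slope)
#' is extrapolated to lambda = -1 (zero measurement error). The SE comes
#' from a jackknife over simulation batches.
#'
#' @param iv an [mr_instruments] table with K >= 3.
#' @param lambda_grid positive noise-inflation factors (>= 2 values;
#'   default 0.5, 1, 1.5, 2).
#' @param n_sim perturbed datasets per lambda (default 1000).
#' @param seed RNG seed.
#' @param n_batches jackknife batches (default 10).
#' @return list with `estimate` (corrected slope), `se`, `ci`, `p`,
#'   `raw_estimate`, and the per-lambda mean slopes.
#' @export
simex_egger <- function(iv, lambda_grid = c(0.5, 1, 1.5, 2), n_sim = 1000L,
                        seed = 1L, n_batches = 10L) {
  K <- nrow(iv)
  if (K < 3) stopf("SIMEX-Egger needs >= 3 instruments")
  lambda_grid <- sort(unique(lambda_grid[lambda_grid > 0]))
  if (length(lambda_grid) < 2) {
    stopf("lambda_grid needs >= 2 positive values (>= 3 grid points with lambda = 0)")
  }
  raw <- mr_egger(iv)$estimate
  if (all(iv$se_bx == 0)) {
    return(list(estimate = raw, se = mr_egger(iv)$se, ci = ci95(raw, mr_egger(iv)$se),
                p = mr_egger(iv)$p, raw_estimate = raw,
                lambda = c(0, lambda_grid), mean_slopes = rep(raw, 1 + length(lambda_grid)),
                extrapolation = "none_needed"))
  }
  egger_slope <- function(bx, by, se_by) {
    flip <- sign(bx); flip[flip == 0] <- 1
    wls_fit(cbind(bx * flip, 1), by * flip, 1 / se_by^2)$coef[1]
  }
  batch <- rep(seq_len(n_batches), length.out = n_sim)
  slopes <- with_seed(seed, {
    vapply(lambda_grid, function(lam) {
      vapply(seq_len(n_sim), function(s) {
        bx_s <- iv$bx + stats::rnorm(K, 0, sqrt(lam) * iv$se_bx)
        egger_slope(bx_s, iv$by, iv$se_by)
      }, numeric(1))
    }, numeric(n_sim))   # n_sim x n_lambda
  })
  extrapolate <- function(mean_slopes) {
    lam <- c(0, lambda_grid)
    y <- c(raw, mean_slopes)
    fit <- tryCatch(stats::lm(y ~ lam + I(lam^2)), error = function(e) NULL)
    if (is.null(fit) || anyNA(stats::coef(fit))) {
      fit <- stats::lm(y ~ lam)
      warnf("SIMEX: quadratic extrapolation degenerate; using linear")
      return(sum(stats::coef(fit) * c(1, -1)))
    }
    sum(stats::coef(fit) * c(1, -1, 1))
  }
  est <- extrapolate(colMeans(slopes))
  jack <- vapply(seq_len(n_batches), function(b) {
    extrapolate(colMeans(slopes[batch != b, , drop = FALSE]))
  }, numeric(1))
  se <- sqrt((n_batches - 1) / n_batches * sum((jack - mean(jack))^2))
  # simulation-batch jackknife captures Monte-Carlo extrapolation noise;
  # add the raw Egger sampling variance for the reported uncertainty
  se <- sqrt(se^2 + mr_egger(iv)$se^2)
  list(estimate = est, se = se, ci = ci95(est, se),
       p = 2 * stats::pnorm(-abs(est / se)), raw_estimate = raw,
       lambda = c(0, lambda_grid), mean_slopes = c(raw, colMeans(slopes)),
       extrapolation = "quadratic")
}

#' MR-PRESSO: global pleiotropy test and outlier correction
#'
#' The observed residual sum of squares uses leave-one-out IVW slopes:
#' `RSS = sum_j (by_j - b(-j) * bx_j)^2 / se_by_j^2`. The null
#' distribution simulates `by* ~ N(b(-j) * bx_j, se_by_j^2)` and
#' recomputes the RSS (with leave-one-out slopes re-estimated on the
#' simulated data). Per-SNP outlier p-values compare each observed
#' residual contribution with its simulated distribution,
#' Bonferroni-corrected at `outlier_alpha`; the corrected estimate is the
#' IVW on non-outliers.
#'
#' @param iv an [mr_instruments] table with K >= 4.
#' @param n_sim null simulations (default 1000; raise for small p-values).
#' @param seed RNG seed.
#' @param outlier_alpha familywise level of the outlier test (default 0.05).
#' @return list with `global_p`, `outliers` (rsIDs), `corrected` (IVW on
#'   non-outliers) and `raw` (full IVW).
#' @export
mr_presso <- function(iv, n_sim = 1000L, seed = 1L, outlier_alpha = 0.05) {
  K <- nrow(iv)
  if (n_sim < 1) stopf("n_sim must be positive")
  if (K < 4) {
    return(list(global_p = NA_real_, outliers = character(),
                corrected = NULL, raw = NULL, reason = "fewer_than_4_instruments"))
  }
  w <- 1 / iv$se_by^2
  loo_slopes <- function(by) {
    s1 <- sum(iv$bx * by * w)
    s2 <- sum(iv$bx^2 * w)
    (s1 - iv$bx * by * w) / (s2 - iv$bx^2 * w)
  }
  b_loo <- loo_slopes(iv$by)
  contrib_obs <- (iv$by - b_loo * iv$bx)^2 * w
  rss_obs <- sum(contrib_obs)
  mu <- b_loo * iv$bx
  sim <- with_seed(seed, {
    BY <- matrix(stats::rnorm(n_sim * K, mean = rep(mu, each = n_sim),
                              sd = rep(iv$se_by, each = n_sim)), n_sim, K)
    S1 <- BY %*% (iv$bx * w)                       # n_sim x 1
    s2 <- sum(iv$bx^2 * w)
    Bl <- (matrix(S1, n_sim, K) - sweep(BY, 2, iv$bx * w, "*")) /
      matrix(s2 - iv$bx^2 * w, n_sim, K, byrow = TRUE)
    RES <- (BY - Bl * matrix(iv$bx, n_sim, K, byrow = TRUE))^2 *
      matrix(w, n_sim, K, byrow = TRUE)
    list(rss = rowSums(RES), contrib = RES)
  })
  global_p <- (1 + sum(sim$rss >= rss_obs)) / (1 + n_sim)
  # raw simulation proportion: the Bonferroni-corrected outlier test must be
  # able to reject at moderate n_sim (the smoothed floor K/(n_sim+1) cannot)
  p_snp <- vapply(seq_len(K), function(j) {
    mean(sim$contrib[, j] >= contrib_obs[j])
  }, numeric(1))
  outlier <- p_snp * K < outlier_alpha
  outliers <- iv$snp[outlier]
  corrected <- if (any(outlier) && sum(!outlier) >= 2) {
    ivw(iv[!outlier, , drop = FALSE])
  } else {
    NULL
  }
  list(global_p = global_p, outlier_p = stats::setNames(p_snp, iv$snp),
       outliers = outliers, corrected = corrected, raw = ivw(iv), reason = "")
}

#' Steiger directionality filtering
#'
#' Per SNP, the variance explained in the exposure is
#' `r2 = t^2 / (t^2 + n - 2)` with `t = bx/se_bx` (effective n for binary
#' traits); the analogue on the outcome side uses `by/se_by`. A SNP is
#' retained iff it explains more variance in the exposure than the
#' outcome; the IVW estimate is re-run on the retained set. SNPs without
#' sample sizes cannot be tested and are retained with a warning.
#'
#' @param iv an [mr_instruments] table with `n_exposure`, `n_outcome`.
#' @return list with `retained` (filtered [mr_instruments]), `removed`
#'   rsIDs, per-SNP `r2_exposure`/`r2_outcome`, and `ivw_retained`.
#' @export
steiger_filter <- function(iv) {
  r2_of <- function(b, se, n) {
    t2 <- (b / se)^2
    t2 / (t2 + n - 2)
  }
  r2x <- r2_of(iv$bx, iv$se_bx, iv$n_exposure)
  r2y <- r2_of(iv$by, iv$se_by, iv$n_outcome)
  untestable <- is.na(r2x) | is.na(r2y)
  if (any(untestable)) {
    warnf("Steiger: %d SNP(s) without sample sizes retained untested", sum(untestable))
  }
  keep <- untestable | (r2x > r2y)
  retained <- iv[keep, , drop = FALSE]
  list(retained = retained, removed = iv$snp[!keep],
       r2_exposure = stats::setNames(r2x, iv$snp),
       r2_outcome = stats::setNames(r2y, iv$snp),
       ivw_retained = if (nrow(retained) >= 2) ivw(retained) else NULL)
}

#' Leave-one-out IVW analysis
#'
#' @param iv an [mr_instruments] table with K >= 3.
#' @return data frame with one row per left-out SNP plus an `(all)` row.
#' @export
leave_one_out <- function(iv) {
  K <- nrow(iv)
  if (K < 3) stopf("leave-one-out needs >= 3 instruments")
  rows <- lapply(seq_len(K), function(j) {
    f <- ivw(iv[-j, , drop = FALSE])
    data.frame(snp_left_out = iv$snp[j], estimate = f$estimate, se = f$se,
               p = f$p, stringsAsFactors = FALSE)
  })
  full <- ivw(iv)
  rbind(do.call(rbind, rows),
        data.frame(snp_left_out = "(all)", estimate = full$estimate,
                   se = full$se, p = full$p, stringsAsFactors = FALSE))
}

#' Instrument strength (F statistics)
#'
#' @param iv an [mr_instruments] table (may be empty).
#' @return list with per-SNP `f`, `mean_f`, `min_f`, and a weak-instrument
#'   flag (mean F < 10).
#' @export
instrument_strength <- function(iv) {
  if (nrow(iv) == 0) {
    return(list(f = numeric(), mean_f = NA_real_, min_f = NA_real_,
                weak = NA))
  }
  f <- (iv$bx / iv$se_bx)^2
  list(f = stats::setNames(f, iv$snp), mean_f = mean(f), min_f = min(f),
       weak = mean(f) < 10)
}

#' Power of a two-sample MR analysis with a binary outcome
#'
#' `power = Phi( sqrt(n v (1-v) r2) * |ln OR| - z_{1-alpha/s} )` with s = 1
#' for a one-sided and 2 for a two-sided test.
#'
#' @param n outcome sample size.
#' @param v case fraction of the outcome, in (0,1).
#' @param r2 phenotypic variance of the exposure explained by the
#'   instruments (> 0).
#' @param odds_ratio causal odds ratio to detect.
#' @param alpha significance level (default 0.05).
#' @param sided `"one"` (default) or `"two"`.
#' @return power in (0,1).
#' @export
mr_power <- function(n, v, r2, odds_ratio, alpha = 0.05,
                     sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (r2 <= 0) stopf("r2 must be positive")
  if (v <= 0 || v >= 1) stopf("case fraction v must lie in (0,1)")
  s <- if (sided == "one") 1 else 2
  stats::pnorm(sqrt(n * v * (1 - v) * r2) * abs(log(odds_ratio)) -
                 stats::qnorm(1 - alpha / s))
}

#' Multivariable IVW with two exposures
#'
#' Weighted least squares of `by` on the two exposure-effect columns
#' without intercept (weights `1/se_by^2`); SEs scaled by
#' `max(1, sqrt(RSS/(K-2)))`, p-values from a t reference with K-2 df.
#'
#' @param iv_multi data frame with columns `bx1, bx2, by, se_by` (K > 3
#'   rows recommended; K must exceed the exposure count + 1).
#' @return data frame with one row per exposure: estimate, SE, CI, p.
#' @export
mvmr_ivw <- function(iv_multi) {
  K <- nrow(iv_multi)
  if (K < 3) stopf("multivariable IVW needs K > number of exposures + 1")
  X <- cbind(bx1 = iv_multi$bx1, bx2 = iv_multi$bx2)
  f <- wls_fit(X, iv_multi$by, 1 / iv_multi$se_by^2)
  cf <- unname(f$coef)
  se <- unname(sqrt(diag(f$vcov)))
  p <- 2 * stats::pt(-abs(cf / se), df = max(K - 2, 1))
  data.frame(exposure = c("exposure1", "exposure2"), estimate = cf,
             se = se, ci_lower = cf - 1.96 * se,
             ci_upper = cf + 1.96 * se, p = p, row.names = NULL)
}

#' Run the full MR sensitivity battery on an instrument set
#'
#' @param iv an [mr_instruments] table.
#' @param n_boot weighted-median bootstrap replicates.
#' @param n_sim MR-PRESSO / SIMEX simulations.
#' @param seed RNG seed.
#' @param run_simex run SIMEX-Egger (default: only when I2_GX flags it or
#'   `TRUE` is passed).
#' @return list of class `mr_bundle` with every estimator's output.
#' @export
mr_battery <- function(iv, n_boot = 1000L, n_sim = 1000L, seed = 1L,
                       run_simex = NULL) {
  K <- nrow(iv)
  out <- list(k = K, instruments = iv)
  out$strength <- instrument_strength(iv)
  if (K < 1) { out$reason <- "no_instruments"; class(out) <- "mr_bundle"; return(out) }
  out$ivw <- ivw(iv)
  out$ivw_fixed <- if (K >= 2) ivw(iv, "fixed") else out$ivw
  out$cochran_q <- if (K >= 2) cochran_q(iv, out$ivw$estimate) else NULL
  out$funnel <- funnel_data(iv)
  out$egger <- if (K >= 3) mr_egger(iv) else list(reason = "fewer_than_3_instruments")
  out$weighted_median <- if (K >= 3) {
    weighted_median(iv, n_boot, child_seed(seed, 1))
  } else NULL
  out$i2_gx <- if (K >= 2) i2_gx(iv) else NULL
  do_simex <- run_simex %||% (K >= 3 && isTRUE(out$i2_gx$simex_recommended))
  out$egger_simex <- if (do_simex && K >= 3) {
    simex_egger(iv, n_sim = n_sim, seed = child_seed(seed, 2))
  } else NULL
  out$presso <- if (K >= 4) {
    mr_presso(iv, n_sim = n_sim, seed = child_seed(seed, 3))
  } else list(reason = "fewer_than_4_instruments")
  out$steiger <- steiger_filter(iv)
  out$loo <- if (K >= 3) leave_one_out(iv) else NULL
  class(out) <- "mr_bundle"
  out
}

#' @export
print.mr_bundle <- function(x, ...) {
  cat(sprintf("MR bundle: K = %d instruments (mean F %.1f)\n", x$k,
              x$strength$mean_f))
  if (!is.null(x$ivw)) {
    cat(sprintf("  IVW: %.4f (SE %.4f, p %.3g)  OR %.3f [%.3f, %.3f]\n",
                x$ivw$estimate, x$ivw$se, x$ivw$p, exp(x$ivw$estimate),
                exp(x$ivw$ci[1]), exp(x$ivw$ci[2])))
  }
  invisible(x)
}

#' Bidirectional two-sample MR from full summary statistics
#'
#' Forward direction: instruments are the exposure's genome-wide
#' significant SNPs (p < `p_threshold`) clumped to independence
#' (r² < `clump_r2` within `clump_kb` kb), harmonized against the outcome
#' and Steiger-filtered; the full battery is run on the filtered set.
#' Reverse direction swaps the roles.
#'
#' @param ss_exposure,ss_outcome [sumstats] objects.
#' @param ld an `ld_panel` for clumping.
#' @param p_threshold instrument selection threshold (default 5e-8).
#' @param clump_r2 clumping r² (default 0.01).
#' @param clump_kb clumping window (default 500 kb).
#' @param seed RNG seed for the stochastic sensitivity analyses.
#' @param ... passed to [mr_battery].
#' @return list with `forward` and `reverse` `mr_bundle`s (each may carry
#'   a `reason` when fewer than 3 instruments survive).
#' @export
bidirectional_mr <- function(ss_exposure, ss_outcome, ld, p_threshold = 5e-8,
                             clump_r2 = 0.01, clump_kb = 500, seed = 1L, ...) {
  one_direction <- function(ss_x, ss_y, dir_seed) {
    cand <- data.frame(snp = ss_x$snp, chrom = ss_x$chrom, pos = ss_x$pos,
                       p = ss_x$p)[ss_x$p < p_threshold, , drop = FALSE]
    if (nrow(cand) == 0) {
      out <- list(k = 0, reason = "no_genomewide_significant_instruments")
      class(out) <- "mr_bundle"
      return(out)
    }
    sentinels <- vapply(clump(cand, ld, p1 = p_threshold, p2 = p_threshold,
                              r2 = clump_r2, kb = clump_kb),
                        function(x) x$sentinel, character(1))
    hp <- harmonize_pair(ss_x[ss_x$snp %in% sentinels, , drop = FALSE], ss_y)
    n_out <- if (!all(is.na(ss_y$n_case))) {
      effective_n(stats::median(ss_y$n_case, na.rm = TRUE),
                  stats::median(ss_y$n_control, na.rm = TRUE))
    } else stats::median(hp$n2)
    iv <- mr_instruments(snp = hp$snp, bx = hp$beta1, se_bx = hp$se1,
                         by = hp$beta2, se_by = hp$se2, eaf = hp$eaf1,
                         n_exposure = stats::median(hp$n1), n_outcome = n_out,
                         palindromic = hp$palindromic)
    st <- steiger_filter(iv)
    if (nrow(st$retained) < 3) {
      out <- list(k = nrow(st$retained), steiger = st,
                  reason = "fewer_than_3_instruments_after_steiger")
      class(out) <- "mr_bundle"
      return(out)
    }
    mr_battery(st$retained, seed = dir_seed, ...)
  }
  list(forward = one_direction(ss_exposure, ss_outcome, child_seed(seed, 11)),
       reverse = one_direction(ss_outcome, ss_exposure, child_seed(seed, 12)))
}
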