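#' LD-score regression: SNP heritability and genetic correlation
#'
#' The univariate model regresses per-SNP association chi-square on
#' `n * l_j / m` (sample size times LD score over SNP count): the slope is
#' the SNP heritability and the free intercept captures confounding /
#' inflation. The bivariate model regresses the z-score product of two
#' traits on `sqrt(n1 * n2) * l_j / m`: the slope is the genetic
#' covariance and the intercept the sample-overlap term. The genetic
#' correlation is `rg = gencov / sqrt(h2_1 * h2_2)`; its SE comes from a
#' delete-one-block jackknife over genomically contiguous SNP blocks in
#' which the full ratio is re-estimated per deletion.
#'
#' @name ldsc
NULL

# Normalize an LD input (ld_panel or data.frame from read_ld_scores) to a
# (snp, ld_score) table.
get_ld_scores <- function(ld) {
  if (inherits(ld, "ld_panel")) {
    return(ld$snps[, c("snp", "chrom", "pos", "ld_score")])
  }
  if (is.data.frame(ld) && all(c("snp", "ld_score") %in% names(ld))) return(ld)
  stopf("`ld` must be an ld_panel or a data frame with columns snp, ld_score")
}

# Predicted E[chi2] used inside the heteroskedasticity weights; clamped so
# weights stay finite and positive even with a negative first-pass slope.
ldsc_pred <- function(n_scaled_l, slope, icept) {
  pmax(n_scaled_l * slope + icept, 0.05)
}

# Weighted regression y ~ x (+ intercept) with per-block sufficient
# statistics for the delete-one-block jackknife (weights held fixed).
ldsc_wls_jack <- function(x, y, w, block, free_intercept = TRUE, offset = 0) {
  y <- y - offset
  X <- if (free_intercept) cbind(x = x, icept = 1) else cbind(x = x)
  p <- ncol(X)
  B <- max(block)
  XtWX_b <- array(0, c(p, p, B))
  XtWy_b <- matrix(0, p, B)
  for (b in seq_len(B)) {
    i <- which(block == b)
    Xb <- X[i, , drop = FALSE]
    XtWX_b[, , b] <- crossprod(Xb * w[i], Xb)
    XtWy_b[, b] <- crossprod(Xb * w[i], y[i])
  }
  XtWX <- apply(XtWX_b, c(1, 2), sum)
  XtWy <- rowSums(XtWy_b)
  coef <- drop(solve(XtWX, XtWy))
  del <- matrix(NA_real_, B, p)
  for (b in seq_len(B)) {
    del[b, ] <- drop(solve(XtWX - XtWX_b[, , b], XtWy - XtWy_b[, b]))
  }
  if (!free_intercept) {
    coef <- c(coef, offset)
    del <- cbind(del, offset)
  } else {
    coef[2] <- coef[2] + offset
    del[, 2] <- del[, 2] + offset
  }
  se <- sqrt((B - 1) / B * colSums(sweep(del, 2, colMeans(del))^2))
  list(coef = coef, se = se, delete_values = del, n_blocks = B)
}

# Contiguous jackknife block assignment over genomically sorted SNPs.
make_blocks <- function(n_snps, n_blocks) {
  if (n_snps < n_blocks) stopf("fewer SNPs (%d) than jackknife blocks (%d)", n_snps, n_blocks)
  as.integer(cut(seq_len(n_snps), breaks = n_blocks, labels = FALSE))
}

# Shared per-trait preparation: merge with LD scores, order genomically,
# chi-square QC.
ldsc_prepare <- function(z, n, snp, chrom, pos, ld_tab, max_chi2 = NULL) {
  i <- match(snp, ld_tab$snp)
  keep <- !is.na(i)
  d <- data.frame(snp = snp[keep], chrom = chrom[keep], pos = pos[keep],
                  z = z[keep], l = ld_tab$ld_score[i[keep]])
  d <- d[order(d$chrom, d$pos), , drop = FALSE]
  lim <- max_chi2 %||% max(80, 0.001 * n)
  d[d$z^2 <= lim, , drop = FALSE]
}

#' Estimate SNP heritability by LD-score regression
#'
#' @param ss a [sumstats] object.
#' @param ld an `ld_panel` or LD-score table ([read_ld_scores]).
#' @param n_blocks jackknife blocks (default 200, contiguous).
#' @param intercept `"free"` (default) or `"fixed"` (constrained to 1).
#' @param max_chi2 chi-square QC ceiling; default `max(80, 0.001 * n)`.
#' @return list with `h2, h2_se, intercept, intercept_se, m_snps, n_blocks`
#'   and the per-block delete values, class `ldsc_h2`.
#' @export
estimate_h2 <- function(ss, ld, n_blocks = 200L, intercept = c("free", "fixed"),
                        max_chi2 = NULL) {
  intercept <- match.arg(intercept)
  ld_tab <- get_ld_scores(ld)
  n <- stats::median(ss$n)
  d <- ldsc_prepare(ss$beta / ss$se, n, ss$snp, ss$chrom, ss$pos, ld_tab, max_chi2)
  m <- nrow(d)
  if (m < 200) stopf("need >= 200 SNPs with LD scores (have %d)", m)
  block <- make_blocks(m, n_blocks)
  x <- n * d$l / m
  chi2 <- d$z^2
  free <- intercept == "free"
  # pass 1: inverse-LD weights
  w0 <- 1 / pmax(d$l, 1)
  f0 <- ldsc_wls_jack(x, chi2, w0, block, free_intercept = free, offset = if (free) 0 else 1)
  slope0 <- f0$coef[1]; icept0 <- f0$coef[2]
  # pass 2: heteroskedasticity-aware weights from the pass-1 fit
  pred <- ldsc_pred(x, max(slope0, 0), max(icept0, 0.1))
  w <- 1 / (2 * pred^2 * pmax(d$l, 1))
  f <- ldsc_wls_jack(x, chi2, w, block, free_intercept = free, offset = if (free) 0 else 1)
  structure(list(h2 = f$coef[1], h2_se = f$se[1],
                 intercept = f$coef[2], intercept_se = f$se[2],
                 m_snps = m, n_blocks = f$n_blocks,
                 delete_values = f$delete_values,
                 pass1 = c(slope = slope0, icept = icept0)),
            class = "ldsc_h2")
}

#' Estimate genetic correlation between two traits
#'
#' Harmonizes the two traits, applies a joint chi-square QC, runs the two
#' univariate and the bivariate LD-score regressions on the same SNP set,
#' and jackknifes the full ratio `rg = gencov / sqrt(h2_1 * h2_2)`.
#' The estimate is deliberately not clamped to \[-1, 1\]; out-of-range
#' values are flagged instead (estimator noise can exceed the bounds).
#'
#' @param ss1,ss2 [sumstats] objects.
#' @param ld an `ld_panel` or LD-score table.
#' @param n_blocks jackknife blocks.
#' @param intercept `"free"` (default) estimates all intercepts;
#'   `"fixed"` constrains univariate intercepts to 1 and the cross
#'   intercept to 0 (no sample overlap).
#' @return An object of class `rg_result`.
#' @export
estimate_rg <- function(ss1, ss2, ld, n_blocks = 200L,
                        intercept = c("free", "fixed")) {
  intercept <- match.arg(intercept)
  free <- intercept == "free"
  ld_tab <- get_ld_scores(ld)
  hp <- harmonize_pair(ss1, ss2)
  n1 <- stats::median(hp$n1); n2 <- stats::median(hp$n2)
  i <- match(hp$snp, ld_tab$snp)
  keep <- !is.na(i)
  d <- data.frame(snp = hp$snp, chrom = hp$chrom, pos = hp$pos,
                  z1 = hp$beta1 / hp$se1, z2 = hp$beta2 / hp$se2,
                  l = ld_tab$ld_score[i])[keep, , drop = FALSE]
  d <- d[order(d$chrom, d$pos), , drop = FALSE]
  d <- d[d$z1^2 <= max(80, 0.001 * n1) & d$z2^2 <= max(80, 0.001 * n2), , drop = FALSE]
  m <- nrow(d)
  if (m < 200) stopf("need >= 200 harmonized SNPs with LD scores (have %d)", m)
  block <- make_blocks(m, n_blocks)
  x1 <- n1 * d$l / m
  x2 <- n2 * d$l / m
  xg <- sqrt(n1 * n2) * d$l / m
  linv <- 1 / pmax(d$l, 1)

  fit_trait <- function(x, chi2) {
    f0 <- ldsc_wls_jack(x, chi2, linv, block, free_intercept = free,
                        offset = if (free) 0 else 1)
    pred <- ldsc_pred(x, max(f0$coef[1], 0), max(f0$coef[2], 0.1))
    w <- 1 / (2 * pred^2 * pmax(d$l, 1))
    list(pass1 = f0$coef,
         fit = ldsc_wls_jack(x, chi2, w, block, free_intercept = free,
                             offset = if (free) 0 else 1),
         pred = pred)
  }
  t1 <- fit_trait(x1, d$z1^2)
  t2 <- fit_trait(x2, d$z2^2)
  # bivariate pass 1 with inverse-LD weights, then product-form weights
  g0 <- ldsc_wls_jack(xg, d$z1 * d$z2, linv, block, free_intercept = free, offset = 0)
  pred_x <- xg * g0$coef[1] + g0$coef[2]
  wg <- 1 / (pmax(d$l, 1) * pmax(t1$pred * t2$pred + pred_x^2, 0.05))
  g <- ldsc_wls_jack(xg, d$z1 * d$z2, wg, block, free_intercept = free, offset = 0)

  h2_1 <- t1$fit$coef[1]; h2_2 <- t2$fit$coef[1]; gencov <- g$coef[1]
  flagged <- character()
  if (h2_1 <= 0 || h2_2 <= 0) flagged <- c(flagged, "nonpositive_h2")
  rg <- if (length(flagged)) NA_real_ else gencov / sqrt(h2_1 * h2_2)
  rg_se <- NA_real_
  if (!length(flagged)) {
    d1 <- t1$fit$delete_values[, 1]
    d2 <- t2$fit$delete_values[, 1]
    dg <- g$delete_values[, 1]
    ok <- d1 > 0 & d2 > 0
    rg_del <- dg[ok] / sqrt(d1[ok] * d2[ok])
    B <- sum(ok)
    if (B < n_blocks) warnf("rg jackknife: %d blocks dropped (nonpositive h2)", n_blocks - B)
    rg_se <- sqrt((B - 1) / B * sum((rg_del - mean(rg_del))^2))
    if (abs(rg) > 1) flagged <- c(flagged, "rg_out_of_range")
  }
  p <- if (is.na(rg) || rg_se <= 0) NA_real_ else 2 * stats::pnorm(-abs(rg / rg_se))
  structure(list(
    h2_1 = h2_1, h2_1_se = t1$fit$se[1], intercept_1 = t1$fit$coef[2],
    h2_2 = h2_2, h2_2_se = t2$fit$se[1], intercept_2 = t2$fit$coef[2],
    gencov = gencov, gencov_se = g$se[1], cross_intercept = g$coef[2],
    cross_intercept_se = g$se[2],
    rg = rg, rg_se = rg_se, p = p, m_snps = m, n_blocks = n_blocks,
    intercept_mode = intercept, flags = flagged
  ), class = "rg_result")
}

#' @export
print.rg_result <- function(x, ...) {
  cat(sprintf("rg = %.4f (SE %.4f), p = %.3g  [gencov %.4f, h2 %.4f / %.4f, %d SNPs]\n",
              x$rg, x$rg_se, x$p, x$gencov, x$h2_1, x$h2_2, x$m_snps))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Label p-values by a Bonferroni gate
#'
#' `"significant"` when `p < 0.05/k_tests`, `"suggestive"` when
#' `0.05/k_tests <= p < 0.05`, else `"ns"`. Boundaries are exclusive.
#'
#' @param p_values numeric p-values.
#' @param k_tests number of tests in the family (>= 1).
#' @return character vector of labels.
#' @export
bonferroni_gate <- function(p_values, k_tests) {
  if (k_tests < 1) stopf("k_tests must be >= 1")
  thr <- 0.05 / k_tests
  ifelse(p_values < thr, "significant",
         ifelse(p_values < 0.05, "suggestive", "ns"))
}
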