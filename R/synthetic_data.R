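#' Ground-truth parameters for synthetic GWAS pairs
#'
#' Collects the generative parameters for a pair of traits: per-trait SNP
#' heritability, their genetic correlation, sample sizes and overlap, and
#' the Mendelian-randomisation scenario parameters (causal effect,
#' balanced/directional pleiotropy, gross outliers). The defaults emulate
#' a large quantitative-trait GWAS pair at biobank scale: 10,000 SNPs,
#' n = 50,000 per trait, h² = 0.3 each, genetic correlation 0.31, no
#' sample overlap — the regime of the type 2 diabetes / PCOS analyses the
#' package targets.
#'
#' @param m SNP count.
#' @param n1,n2 GWAS sample sizes.
#' @param h2_1,h2_2 SNP heritabilities in \[0,1\].
#' @param rg_true genetic correlation in \[-1,1\].
#' @param n_overlap shared samples between the two GWAS.
#' @param rho_pheno phenotypic correlation within the overlap.
#' @param causal_b causal effect of trait 1 on trait 2 (log-OR units for a
#'   binary outcome).
#' @param pleio_mean,pleio_sd mean and SD of per-instrument direct
#'   (horizontal pleiotropy) effects in MR scenarios; a nonzero mean is
#'   directional pleiotropy.
#' @param n_outliers number of instruments given an additional gross
#'   direct effect.
#' @param n_case1,n_control1,n_case2,n_control2 optional case/control
#'   splits for binary traits (effective n is then used internally).
#' @return An object of class `sim_truth`.
#' @export
sim_truth <- function(m = 10000L, n1 = 50000, n2 = 50000,
                      h2_1 = 0.3, h2_2 = 0.3, rg_true = 0.31,
                      n_overlap = 0, rho_pheno = 0,
                      causal_b = 0, pleio_mean = 0, pleio_sd = 0,
                      n_outliers = 0L,
                      n_case1 = NA, n_control1 = NA,
                      n_case2 = NA, n_control2 = NA) {
  if (h2_1 < 0 || h2_1 > 1 || h2_2 < 0 || h2_2 > 1) stopf("h2 must lie in [0,1]")
  if (abs(rg_true) > 1) stopf("|rg_true| must be <= 1")
  if (n_overlap > min(n1, n2)) stopf("n_overlap cannot exceed min(n1, n2)")
  if (abs(rho_pheno) > 1) stopf("|rho_pheno| must be <= 1")
  structure(list(m = as.integer(m), n1 = n1, n2 = n2, h2_1 = h2_1, h2_2 = h2_2,
                 rg_true = rg_true, n_overlap = n_overlap,
                 rho_pheno = rho_pheno, causal_b = causal_b,
                 pleio_mean = pleio_mean, pleio_sd = pleio_sd,
                 n_outliers = as.integer(n_outliers),
                 n_case1 = n_case1, n_control1 = n_control1,
                 n_case2 = n_case2, n_control2 = n_control2),
            class = "sim_truth")
}

#' Simulate a coupled pair of GWAS summary-statistics sets
#'
#' Per-SNP true effects are drawn bivariate normal on the standardized
#' (unit-variance genotype) scale with `Var(beta_t) = h2_t / m` and
#' `Cov = rg_true * sqrt(h2_1 * h2_2) / m`. Within each LD region the
#' observed z-vector is `sqrt(n_t) * R %*% beta_t` plus correlated MVN(0, R)
#' noise; the cross-trait noise correlation is
#' `rho_pheno * n_overlap / sqrt(n1 * n2)` (the sample-overlap term).
#' Betas and SEs are back-filled on the standardized scale as
#' `beta = z / sqrt(n)`, `se = 1 / sqrt(n)`; p-values are two-sided.
#'
#' @param truth a [sim_truth].
#' @param panel an `ld_panel`; its SNP count must equal `truth$m`.
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @return `list(ss1 =, ss2 =)` of [sumstats] objects.
#' @export
simulate_pair <- function(truth, panel, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"), inherits(panel, "ld_panel"))
  m <- nrow(panel$snps)
  if (m != truth$m) stopf("panel has %d SNPs but truth$m = %d", m, truth$m)
  rho_ov <- truth$rho_pheno * truth$n_overlap / sqrt(truth$n1 * truth$n2)
  if (abs(rho_ov) > 1) stopf("implied overlap correlation outside [-1, 1]")
  cov_b <- truth$rg_true * sqrt(truth$h2_1 * truth$h2_2) / m
  Sigma_b <- matrix(c(truth$h2_1 / m, cov_b, cov_b, truth$h2_2 / m), 2)
  ev <- eigen(Sigma_b, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12) stopf("implied effect covariance is not positive semi-definite")

  with_seed(seed, {
    A <- chol_psd(Sigma_b)           # 2x2, Sigma_b = A %*% t(A)
    B <- matrix(stats::rnorm(2L * m), nrow = m) %*% t(A)  # m x 2 true betas
    z1 <- numeric(m); z2 <- numeric(m)
    for (r in seq_len(nrow(panel$regions))) {
      idx <- which(panel$snps$region == r)
      Rm <- panel$R[[r]]
      L <- chol_psd(Rm)
      e_raw <- matrix(stats::rnorm(2L * length(idx)), ncol = 2)
      e1 <- drop(L %*% e_raw[, 1])
      e2 <- drop(L %*% (rho_ov * e_raw[, 1] + sqrt(1 - rho_ov^2) * e_raw[, 2]))
      z1[idx] <- sqrt(truth$n1) * drop(Rm %*% B[idx, 1]) + e1
      z2[idx] <- sqrt(truth$n2) * drop(Rm %*% B[idx, 2]) + e2
    }
    list(
      ss1 = z_to_sumstats(panel, z1, truth$n1, truth$n_case1, truth$n_control1),
      ss2 = z_to_sumstats(panel, z2, truth$n2, truth$n_case2, truth$n_control2)
    )
  })
}

# Lower-triangular factor tolerant of semi-definite matrices.
chol_psd <- function(S) {
  out <- tryCatch(t(chol(S)), error = function(e) NULL)
  if (!is.null(out)) return(out)
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(lam), length(lam))
}

z_to_sumstats <- function(panel, z, n, n_case = NA, n_control = NA) {
  se <- 1 / sqrt(n)
  sumstats(
    snp = panel$snps$snp, chrom = panel$snps$chrom, pos = panel$snps$pos,
    a1 = "A", a2 = "G", eaf = 0.3,
    beta = z * se, se = se, p = 2 * stats::pnorm(-abs(z)), n = n,
    n_case = n_case, n_control = n_control, validate = FALSE
  )
}

#' Simulate a two-sample MR instrument set with known causal structure
#'
#' True instrument-exposure effects are drawn `bx ~ N(0.08, 0.02^2)`
#' (strong, positively oriented instruments, as genome-wide-significant
#' index SNPs are); the true outcome effect per SNP is
#' `by = causal_b * bx + alpha_j` with direct effects
#' `alpha_j ~ N(pleio_mean, pleio_sd^2)` independent of `bx` (the InSIDE
#' condition holds). The first `n_outliers` SNPs receive an additional
#' gross direct effect of magnitude 0.3 with alternating sign. Observed
#' effects add `N(0, se^2)` measurement noise with `se_bx = 1/sqrt(n1)`,
#' `se_by = 1/sqrt(n2)` (effective n when case/control splits are given);
#' `noise = FALSE` returns the error-free effects (SEs still reported).
#'
#' @param truth a [sim_truth].
#' @param k number of instruments (>= 3).
#' @param seed RNG seed.
#' @param noise add measurement noise to the observed effects?
#' @return An object of class `mr_instruments`: a data frame with columns
#'   `snp, bx, se_bx, by, se_by, n_exposure, n_outcome, v_case_out`.
#' @export
simulate_instruments <- function(truth, k, seed = 1L, noise = TRUE) {
  stopifnot(inherits(truth, "sim_truth"))
  if (k < 3) stopf("need at least 3 instruments")
  n_exp <- if (!is.na(truth$n_case1)) effective_n(truth$n_case1, truth$n_control1) else truth$n1
  n_out <- if (!is.na(truth$n_case2)) effective_n(truth$n_case2, truth$n_control2) else truth$n2
  se_bx <- rep(1 / sqrt(n_exp), k)
  se_by <- rep(1 / sqrt(n_out), k)
  v_case <- if (!is.na(truth$n_case2)) truth$n_case2 / (truth$n_case2 + truth$n_control2) else NA_real_
  with_seed(seed, {
    bx_true <- stats::rnorm(k, mean = 0.08, sd = 0.02)
    alpha <- stats::rnorm(k, mean = truth$pleio_mean, sd = truth$pleio_sd)
    by_true <- truth$causal_b * bx_true + alpha
    if (truth$n_outliers > 0) {
      io <- seq_len(min(truth$n_outliers, k))
      by_true[io] <- by_true[io] + 0.3 * (-1)^(io + 1)
    }
    bx <- if (noise) bx_true + stats::rnorm(k, 0, se_bx) else bx_true
    by <- if (noise) by_true + stats::rnorm(k, 0, se_by) else by_true
    mr_instruments(snp = paste0("iv", seq_len(k)), bx = bx, se_bx = se_bx,
                   by = by, se_by = se_by, n_exposure = n_exp,
                   n_outcome = n_out, v_case_out = v_case)
  })
}

#' Simulate sparse expression-weight vectors over an LD panel
#'
#' Each gene gets a weight vector supported on a random subset of the SNPs
#' of one region (genes are assigned to regions round-robin); nonzero
#' weights are standard normal. A designated subset of genes is marked
#' truly trait-associated, for use with [spike_twas_z].
#'
#' @param panel an `ld_panel`.
#' @param n_genes number of genes.
#' @param sparsity fraction of region SNPs carrying nonzero weight, in (0,1].
#' @param n_causal number of genes designated truly associated.
#' @param seed RNG seed.
#' @return `list(weights =, genes =, causal_genes =)`: `weights` is a named
#'   list of data frames `(snp, weight)`; `genes` maps gene to region.
#' @export
simulate_twas_weights <- function(panel, n_genes, sparsity = 0.2,
                                  n_causal = 0L, seed = 1L) {
  stopifnot(inherits(panel, "ld_panel"))
  if (sparsity <= 0 || sparsity > 1) stopf("sparsity must lie in (0, 1]")
  n_regions <- nrow(panel$regions)
  with_seed(seed, {
    genes <- data.frame(
      gene = sprintf("gene%03d", seq_len(n_genes)),
      region = rep_len(seq_len(n_regions), n_genes),
      stringsAsFactors = FALSE
    )
    weights <- lapply(seq_len(n_genes), function(g) {
      snps <- panel$snps$snp[panel$snps$region == genes$region[g]]
      k <- max(1L, round(sparsity * length(snps)))
      pick <- sort(sample.int(length(snps), k))
      w <- stats::rnorm(k)
      while (all(w == 0)) w <- stats::rnorm(k)   # reject all-zero vectors
      data.frame(snp = snps[pick], weight = w, stringsAsFactors = FALSE)
    })
    names(weights) <- genes$gene
    causal <- if (n_causal > 0) genes$gene[seq_len(min(n_causal, n_genes))] else character()
    list(weights = weights, genes = genes, causal_genes = causal)
  })
}

#' Spike GWAS z-scores along chosen genes' weighted directions
#'
#' Generates a null z-vector (MVN(0, R) per region) and adds
#' `lambda * R w / sqrt(w'Rw)` for each causal gene, so the expected TWAS
#' z-score of a causal gene is `lambda`.
#'
#' @param panel an `ld_panel`.
#' @param tw output of [simulate_twas_weights].
#' @param lambda non-centrality of each causal gene's TWAS z-score.
#' @param seed RNG seed.
#' @return Named numeric z-vector over the panel's SNPs.
#' @export
spike_twas_z <- function(panel, tw, lambda = 6, seed = 1L) {
  m <- nrow(panel$snps)
  z <- with_seed(seed, {
    out <- numeric(m)
    for (r in seq_len(nrow(panel$regions))) {
      idx <- which(panel$snps$region == r)
      L <- chol_psd(panel$R[[r]])
      out[idx] <- drop(L %*% stats::rnorm(length(idx)))
    }
    out
  })
  names(z) <- panel$snps$snp
  for (g in tw$causal_genes) {
    wdf <- tw$weights[[g]]
    region <- tw$genes$region[tw$genes$gene == g]
    snps_r <- panel$snps$snp[panel$snps$region == region]
    Rm <- panel$R[[region]]
    w <- numeric(length(snps_r)); names(w) <- snps_r
    w[wdf$snp] <- wdf$weight
    denom <- sqrt(drop(t(w) %*% Rm %*% w))
    z[snps_r] <- z[snps_r] + lambda * drop(Rm %*% w) / denom
  }
  z
}
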