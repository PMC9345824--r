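#' Cross-phenotype association meta-analysis
#'
#' Per SNP, trait z-scores are combined with sample-size weights under a
#' trait-trait correlation matrix estimated from null SNPs. The
#' homogeneous-effects statistic is
#' `S_Hom = (w' R^-1 z)^2 / (w' R^-1 w)` (chi-square, 1 df). The
#' heterogeneous-effects statistic `S_Het` maximizes `S_Hom` over the
#' trait subsets selected by thresholding |z|, and its null distribution
#' is a gamma fit to Monte-Carlo draws of `S_Het` under z ~ MVN(0, R).
#'
#' @name cpassoc
NULL

#' Trait-trait correlation of association statistics
#'
#' Pearson correlation of per-SNP z-scores across traits, restricted to
#' SNPs that are null in every trait (|z| < 1.96), which captures sample
#' overlap / relatedness rather than genetic signal. With fewer than 100
#' null SNPs a warning is issued and all SNPs are used.
#'
#' @param z_mat numeric matrix, SNPs x traits, of aligned z-scores.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
estimate_stat_correlation <- function(z_mat) {
  z_mat <- as.matrix(z_mat)
  if (ncol(z_mat) == 1L) return(matrix(1, 1, 1))
  null_rows <- rowSums(abs(z_mat) >= 1.96) == 0
  if (sum(null_rows) < 100) {
    warnf("only %d null SNPs (<100); falling back to all SNPs", sum(null_rows))
    null_rows <- rep(TRUE, nrow(z_mat))
  }
  R <- stats::cor(z_mat[null_rows, , drop = FALSE])
  diag(R) <- 1
  R
}

check_R_invertible <- function(R) {
  cn <- kappa(R, exact = TRUE)
  if (!is.finite(cn) || cn > 1e10) {
    off <- which(abs(R) > 0.999 & row(R) < col(R), arr.ind = TRUE)
    pair <- if (nrow(off)) sprintf(" (traits %d and %d collinear)", off[1, 1], off[1, 2]) else ""
    stopf("trait correlation matrix is singular%s", pair)
  }
}

#' Homogeneous-effects cross-phenotype statistic
#'
#' @param z per-trait z-vector for one SNP (aligned to a common effect
#'   allele).
#' @param w per-trait weights, conventionally `sqrt(N)` (or `sqrt(N_eff)`
#'   for binary traits).
#' @param R trait-trait correlation matrix of the statistics.
#' @return list with `stat` and `p` (chi-square, 1 df).
#' @export
s_hom <- function(z, w, R) {
  check_R_invertible(R)
  Rinv_w <- solve(R, w)
  stat <- drop(crossprod(Rinv_w, z))^2 / drop(crossprod(Rinv_w, w))
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# S_Het statistic for a single z-vector: maximum of S_Hom over the trait
# subsets selected by |z| > tau across the grid (default: the distinct
# |z| values minus epsilon, plus 0 -- i.e. all "top-j by |z|" subsets).
s_het_stat <- function(z, w, R, tau_grid = NULL) {
  K <- length(z)
  if (all(z == 0)) return(0)
  if (is.null(tau_grid)) {
    tau_grid <- c(0, sort(unique(abs(z)[abs(z) > 0])) - 1e-9)
  }
  if (!any(tau_grid == 0)) stopf("tau_grid must include 0")
  best <- 0
  for (tau in tau_grid) {
    sel <- which(abs(z) > tau)
    if (!length(sel)) sel <- seq_len(K)   # fall back to the full vector
    s <- s_hom(z[sel], w[sel], R[sel, sel, drop = FALSE])$stat
    if (s > best) best <- s
  }
  best
}

#' Fit the Monte-Carlo null distribution of S_Het
#'
#' Draws `null_reps` vectors z ~ MVN(0, R), computes S_Het for each, and
#' fits a gamma distribution by maximum likelihood to the positive draws.
#' The fit can be reused across many [s_het] calls sharing the same R and
#' weights.
#'
#' @param w,R as in [s_hom].
#' @param null_reps Monte-Carlo draws (default 100000).
#' @param seed RNG seed.
#' @return list of class `s_het_null` with `shape`, `rate`, `n_reps`.
#' @export
fit_s_het_null <- function(w, R, null_reps = 100000L, seed = 1L) {
  if (null_reps < 1) stopf("null_reps must be positive")
  check_R_invertible(R)
  K <- nrow(R)
  L <- chol_psd(R)   # lower factor: L %*% t(L) = R
  # precompute the linear form of S_Hom for every trait subset
  subsets <- lapply(seq_len(2^K - 1L), function(mask) {
    sel <- which(bitwAnd(mask, 2^(seq_len(K) - 1L)) > 0)
    Rinv_w <- solve(R[sel, sel, drop = FALSE], w[sel])
    list(sel = sel, a = Rinv_w / sqrt(drop(crossprod(Rinv_w, w[sel]))))
  })
  draws <- with_seed(seed, {
    Z <- t(L %*% matrix(stats::rnorm(K * null_reps), K))  # reps x K
    absZ <- abs(Z)
    ord <- t(apply(absZ, 1, order, decreasing = TRUE))    # reps x K
    S <- numeric(null_reps)
    for (j in seq_len(K)) {
      mask <- as.integer(rowSums(matrix(2^(ord[, seq_len(j), drop = FALSE] - 1L),
                                        ncol = j)))
      for (mk in unique(mask)) {
        rows <- which(mask == mk)
        sub <- subsets[[mk]]
        s_j <- drop(Z[rows, sub$sel, drop = FALSE] %*% sub$a)^2
        S[rows] <- pmax(S[rows], s_j)
      }
    }
    S
  })
  pos <- draws[draws > 0]
  fit <- tryCatch(
    suppressWarnings(MASS::fitdistr(pos, "gamma",
                                    start = list(shape = mean(pos)^2 / stats::var(pos),
                                                 rate = mean(pos) / stats::var(pos)),
                                    lower = c(1e-6, 1e-6))),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    shape <- mean(pos)^2 / stats::var(pos)
    rate <- mean(pos) / stats::var(pos)
  } else {
    shape <- fit$estimate[["shape"]]
    rate <- fit$estimate[["rate"]]
  }
  structure(list(shape = shape, rate = rate, n_reps = null_reps,
                 p_zero = mean(draws <= 0)),
            class = "s_het_null")
}

#' Heterogeneous-effects cross-phenotype statistic
#'
#' @param z,w,R as in [s_hom].
#' @param tau_grid |z| thresholds defining candidate trait subsets; must
#'   include 0. Default: the distinct observed |z| values minus epsilon,
#'   plus 0 (exhaustive for small trait counts).
#' @param null_reps Monte-Carlo draws for the gamma-fitted null (ignored
#'   when `null_fit` is supplied).
#' @param seed RNG seed for the null simulation.
#' @param null_fit optional precomputed [fit_s_het_null] result.
#' @return list with `stat`, `p` (upper tail of the fitted gamma; never
#'   exactly 0), and the `null_fit` used.
#' @export
s_het <- function(z, w, R, tau_grid = NULL, null_reps = 100000L, seed = 1L,
                  null_fit = NULL) {
  stat <- s_het_stat(z, w, R, tau_grid)
  if (is.null(null_fit)) null_fit <- fit_s_het_null(w, R, null_reps, seed)
  p <- stats::pgamma(stat, shape = null_fit$shape, rate = null_fit$rate,
                     lower.tail = FALSE)
  p <- min(max(p, .Machine$double.xmin), 1)
  list(stat = stat, p = p, null_fit = null_fit)
}

#' Screen SNPs for significant pleiotropy
#'
#' A SNP is a pleiotropy candidate when its cross-phenotype meta-analysis
#' p-value is genome-wide significant and at least one single-trait
#' p-value reaches suggestive significance (both single-trait p-values
#' must be finite and below 1). All boundaries are exclusive.
#'
#' @param p_cpassoc cross-phenotype p-values.
#' @param p1,p2 single-trait p-values.
#' @param p_meta_threshold genome-wide threshold (default 5e-8).
#' @param p_single_threshold suggestive single-trait threshold (default 1e-3).
#' @return logical vector: passes the screening rule.
#' @export
screen_pleiotropic <- function(p_cpassoc, p1, p2,
                               p_meta_threshold = 5e-8,
                               p_single_threshold = 1e-3) {
  ok <- p_cpassoc < p_meta_threshold &
    (p1 < p_single_threshold | p2 < p_single_threshold) &
    is.finite(p1) & is.finite(p2) & p1 < 1 & p2 < 1
  ok & !is.na(ok)
}

#' Greedy LD clumping of candidate SNPs
#'
#' Repeatedly takes the unassigned SNP with the smallest p-value below
#' `p1` as a sentinel and assigns to its clump every unassigned SNP with
#' p < `p2`, within `kb` kilobases on the same chromosome, and r² >=
#' `r2` with the sentinel. Ties on p are broken by ascending (chrom, pos).
#' SNP pairs without LD information (different regions) have r² = 0.
#'
#' @param candidates data frame with columns `snp, chrom, pos, p`.
#' @param ld an `ld_panel` supplying pairwise r².
#' @param p1 sentinel p-value threshold (default 5e-8).
#' @param p2 member p-value threshold (default 1e-5).
#' @param r2 LD threshold (default 0.2).
#' @param kb distance window in kilobases (default 500).
#' @return list of clumps, each `list(sentinel, chrom, pos, p, members)`;
#'   empty list when no SNP passes `p1`.
#' @export
clump <- function(candidates, ld, p1 = 5e-8, p2 = 1e-5, r2 = 0.2, kb = 500) {
  d <- candidates[order(candidates$p, candidates$chrom, candidates$pos), , drop = FALSE]
  assigned <- rep(FALSE, nrow(d))
  clumps <- list()
  repeat {
    i <- which(!assigned & d$p < p1)[1]
    if (is.na(i)) break
    mem <- which(!assigned & d$p < p2 & d$chrom == d$chrom[i] &
                   abs(d$pos - d$pos[i]) <= kb * 1000)
    mem <- mem[mem == i | vapply(mem, function(j) {
      panel_r2(ld, d$snp[i], d$snp[j]) >= r2
    }, logical(1))]
    assigned[mem] <- TRUE
    clumps[[length(clumps) + 1L]] <- list(
      sentinel = d$snp[i], chrom = d$chrom[i], pos = d$pos[i], p = d$p[i],
      members = d$snp[mem]
    )
  }
  clumps
}

#' Classify a pleiotropic locus into the four shared-SNP categories
#'
#' Category 1 ("known"): the sentinel is genome-wide significant in both
#' single traits. Category 2 ("single-trait-driven"): genome-wide
#' significant in exactly one trait. Category 3 ("LD-tagged"): in LD
#' (r² > `r2_threshold`) with an index SNP previously identified for
#' either single trait. Category 4 ("novel"): none of the above.
#'
#' @param sentinel sentinel rsID.
#' @param p1,p2 the sentinel's single-trait p-values.
#' @param index1,index2 character vectors of known index SNPs per trait.
#' @param ld an `ld_panel` for sentinel-index r².
#' @param gw_threshold genome-wide significance threshold (default 5e-8).
#' @param r2_threshold LD threshold for category 3 (default 0.2).
#' @return integer category in 1..4.
#' @export
classify_locus <- function(sentinel, p1, p2, index1, index2, ld,
                           gw_threshold = 5e-8, r2_threshold = 0.2) {
  gw1 <- p1 < gw_threshold
  gw2 <- p2 < gw_threshold
  if (gw1 && gw2) return(1L)
  if (gw1 || gw2) return(2L)
  idx <- unique(c(index1, index2))
  if (length(idx)) {
    r2s <- vapply(idx, function(s) panel_r2(ld, sentinel, s), numeric(1))
    if (max(r2s) > r2_threshold) return(3L)
  }
  4L
}

#' Full per-SNP cross-phenotype meta-analysis of a harmonized pair
#'
#' Builds aligned z-vectors, estimates the trait correlation matrix from
#' null SNPs, computes S_Hom and S_Het per SNP (one shared gamma null),
#' screens pleiotropic candidates, clumps them, and classifies each locus.
#'
#' @param hp a `harmonized_pair` (see [harmonize_pair]).
#' @param ld an `ld_panel`.
#' @param index1,index2 known index SNPs per trait (for classification).
#' @param null_reps Monte-Carlo draws for the S_Het null.
#' @param seed RNG seed.
#' @param weights optional per-trait weights (default `sqrt(median n)` per
#'   trait; supply `sqrt(effective_n(...))` for binary traits).
#' @return list with `snp_table` (per-SNP statistics), `r_matrix`,
#'   `candidates`, and `loci` (clumped, classified).
#' @export
cpassoc_scan <- function(hp, ld, index1 = character(), index2 = character(),
                         null_reps = 20000L, seed = 1L, weights = NULL) {
  z1 <- hp$beta1 / hp$se1
  z2 <- hp$beta2 / hp$se2
  Z <- cbind(z1, z2)
  R <- estimate_stat_correlation(Z)
  w <- weights %||% sqrt(c(stats::median(hp$n1), stats::median(hp$n2)))
  null_fit <- fit_s_het_null(w, R, null_reps, seed)
  stats_het <- vapply(seq_len(nrow(Z)), function(i) s_het_stat(Z[i, ], w, R),
                      numeric(1))
  p_het <- pmin(pmax(stats::pgamma(stats_het, shape = null_fit$shape,
                                   rate = null_fit$rate, lower.tail = FALSE),
                     .Machine$double.xmin), 1)
  Rinv_w <- solve(R, w)
  s_hom_all <- drop(Z %*% Rinv_w)^2 / drop(crossprod(Rinv_w, w))
  snp_table <- data.frame(
    snp = hp$snp, chrom = hp$chrom, pos = hp$pos,
    z1 = z1, z2 = z2, p1 = hp$p1, p2 = hp$p2,
    s_hom = s_hom_all,
    p_hom = stats::pchisq(s_hom_all, 1, lower.tail = FALSE),
    s_het = stats_het, p_cpassoc = p_het,
    stringsAsFactors = FALSE
  )
  keep <- screen_pleiotropic(snp_table$p_cpassoc, snp_table$p1, snp_table$p2)
  candidates <- snp_table[keep, , drop = FALSE]
  loci <- list()
  if (nrow(candidates)) {
    cl <- clump(data.frame(snp = candidates$snp, chrom = candidates$chrom,
                           pos = candidates$pos, p = candidates$p_cpassoc),
                ld)
    loci <- lapply(cl, function(lc) {
      i <- match(lc$sentinel, snp_table$snp)
      lc$p_trait1 <- snp_table$p1[i]
      lc$p_trait2 <- snp_table$p2[i]
      lc$category <- classify_locus(lc$sentinel, lc$p_trait1, lc$p_trait2,
                                    index1, index2, ld)
      lc
    })
  }
  list(snp_table = snp_table, r_matrix = R, weights = w,
       candidates = candidates, loci = loci, null_fit = null_fit)
}
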