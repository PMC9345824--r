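# Cross-phenotype meta-analysis: S_Hom, S_Het, screening, clumping,
# classification.

test_that("S_Hom matches hand computation and its degenerate cases", {
  res <- s_hom(c(2, 2), c(1, 1), diag(2))
  expect_equal(res$stat, 8)                       # (1*2+1*2)^2 / 2
  expect_equal(res$p, 0.004678, tolerance = 1e-4) # chi2(1) tail at 8
  expect_equal(s_hom(c(0, 0), c(1, 1), diag(2))$stat, 0)
  expect_equal(s_hom(c(0, 0), c(1, 1), diag(2))$p, 1)
  expect_equal(s_hom(3, 1, matrix(1))$stat, 9)    # K = 1: plain chi-square
  R_sing <- matrix(c(1, 1, 1, 1), 2)
  expect_error(s_hom(c(1, 1), c(1, 1), R_sing), "singular")
})

test_that("S_Het maximizes over threshold-selected subsets", {
  # z = (6, 0): tau just below 6 selects trait 1 alone -> 36 > S_Hom = 18
  stat <- crosstraitr:::s_het_stat(c(6, 0), c(1, 1), diag(2))
  expect_equal(stat, 36)
  expect_gte(stat, s_hom(c(6, 0), c(1, 1), diag(2))$stat)
  expect_equal(crosstraitr:::s_het_stat(c(0, 0), c(1, 1), diag(2)), 0)
  # equal effects: tau = 0 point dominates, S_Het = S_Hom = 2a^2
  a <- 3
  expect_equal(crosstraitr:::s_het_stat(c(a, a), c(1, 1), diag(2)), 2 * a^2)
  # explicit grid must contain 0
  expect_error(crosstraitr:::s_het_stat(c(1, 2), c(1, 1), diag(2),
                                        tau_grid = c(1)), "tau_grid")
})

test_that("S_Het p-values come from the fitted gamma tail and behave", {
  nf <- fit_s_het_null(c(1, 1), diag(2), null_reps = 20000, seed = 5)
  r0 <- s_het(c(0, 0), c(1, 1), diag(2), null_fit = nf)
  expect_equal(r0$stat, 0)
  expect_gt(r0$p, 0.9)
  r1 <- s_het(c(6, 0), c(1, 1), diag(2), null_fit = nf)
  expect_lt(r1$p, 1e-6)
  expect_gt(r1$p, 0)           # the fitted tail never returns exactly 0
  # monotone decreasing in the statistic for a fixed fitted null
  stats <- c(1, 4, 9, 25, 36)
  ps <- vapply(stats, function(s) {
    pgamma(s, nf$shape, nf$rate, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("S_Het test is calibrated at alpha = 0.05 under the MVN null", {
  R <- matrix(c(1, 0.3, 0.3, 1), 2)
  w <- sqrt(c(50000, 80000))
  nf <- fit_s_het_null(w, R, null_reps = 50000, seed = 6)
  set.seed(61)
  L <- t(chol(R))
  reps <- 2000
  rej <- mean(vapply(seq_len(reps), function(i) {
    z <- drop(L %*% rnorm(2))
    s <- crosstraitr:::s_het_stat(z, w, R)
    pgamma(s, nf$shape, nf$rate, lower.tail = FALSE) < 0.05
  }, logical(1)))
  band <- 1.96 * sqrt(0.05 * 0.95 / reps)
  expect_gt(rej, 0.05 - band - 0.01)
  expect_lt(rej, 0.05 + band + 0.01)
})

test_that("statistic correlation reflects sample overlap and has a null floor", {
  panel <- make_ld_panel(ld_block_spec(2000, 1, 0))
  # independent traits: off-diagonal within 2/sqrt(m) of 0
  pair <- simulate_pair(sim_truth(m = 2000L, h2_1 = 0, h2_2 = 0, rg_true = 0),
                        panel, seed = 62)
  Z <- cbind(pair$ss1$beta / pair$ss1$se, pair$ss2$beta / pair$ss2$se)
  R0 <- estimate_stat_correlation(Z)
  expect_lt(abs(R0[1, 2]), 2 / sqrt(2000) * 2)
  # fully overlapping samples with rho_pheno = 0.5
  pair_ov <- simulate_pair(sim_truth(m = 2000L, h2_1 = 0, h2_2 = 0,
                                     rg_true = 0, n_overlap = 50000,
                                     rho_pheno = 0.5), panel, seed = 63)
  Zov <- cbind(pair_ov$ss1$beta / pair_ov$ss1$se,
               pair_ov$ss2$beta / pair_ov$ss2$se)
  Rov <- estimate_stat_correlation(Zov)
  # restricting to jointly null SNPs truncates the bivariate normal and
  # attenuates rho = 0.5 to ~0.41 (the estimator's design trade-off)
  expect_gt(Rov[1, 2], 0.33)
  expect_lt(Rov[1, 2], 0.5)
  expect_equal(estimate_stat_correlation(matrix(rnorm(50), 50, 1)),
               matrix(1, 1, 1))
  expect_warning(estimate_stat_correlation(matrix(rnorm(40) * 10, 20, 2)),
                 "null SNPs")
})

test_that("the pleiotropy screening rule enforces both thresholds strictly", {
  tab <- published_pleiotropic_snps()
  pass <- screen_pleiotropic(tab$p_cpassoc, tab$p_pcos, tab$p_trait)
  expect_true(all(pass))               # all 19 published rows satisfy the rule
  expect_equal(length(unique(tab$snp[pass])), 16L)
  # boundaries are exclusive
  expect_false(screen_pleiotropic(5e-8, 1e-4, 0.5))
  expect_false(screen_pleiotropic(1e-9, 1e-3, 1e-3))
  expect_false(screen_pleiotropic(1e-9, 0.5, 0.5))
  expect_true(screen_pleiotropic(4.9e-8, 9.9e-4, 0.5))
})

test_that("greedy clumping follows the hand-traced assignment", {
  panel <- make_ld_panel(ld_block_spec(2, 3, 0.8), region_size = 3)
  # rs1..rs3 in one block (r2(rs1,rs2) = 0.64, r2(rs1,rs3) = 0.41);
  # rs4 in another region (r2 = 0 with all)
  cand <- data.frame(snp = c("rs1", "rs2", "rs4"), chrom = 1L,
                     pos = c(10000L, 20000L, 40000L),
                     p = c(1e-10, 1e-9, 1e-9))
  cl <- clump(cand, panel, p1 = 5e-8, p2 = 1e-5, r2 = 0.2, kb = 500)
  expect_length(cl, 2)
  expect_equal(cl[[1]]$sentinel, "rs1")
  expect_setequal(cl[[1]]$members, c("rs1", "rs2"))
  expect_equal(cl[[2]]$sentinel, "rs4")
  # mutually unlinked SNPs each form their own clump
  cand2 <- data.frame(snp = c("rs1", "rs4"), chrom = 1L,
                      pos = c(10000L, 40000L), p = c(1e-10, 1e-9))
  expect_length(clump(cand2, panel), 2)
  # single SNP, and no SNP below p1
  expect_length(clump(cand2[1, ], panel), 1)
  cand3 <- cand2; cand3$p <- c(1e-6, 1e-6)
  expect_length(clump(cand3, panel), 0)
})

test_that("clumping output is a partition with unlinked sentinels", {
  panel <- test_panel(20, 10, 0.7)
  set.seed(64)
  snps <- panel$snps
  cand <- data.frame(snp = snps$snp, chrom = snps$chrom, pos = snps$pos,
                     p = 10^-runif(nrow(snps), 0, 12))
  cl <- clump(cand, panel)
  members <- unlist(lapply(cl, `[[`, "members"))
  expect_equal(anyDuplicated(members), 0L)
  sentinels <- vapply(cl, `[[`, character(1), "sentinel")
  for (i in seq_along(sentinels)) {
    for (j in seq_len(i - 1L)) {
      pi <- cand$pos[cand$snp == sentinels[i]]
      pj <- cand$pos[cand$snp == sentinels[j]]
      linked <- panel_r2(panel, sentinels[i], sentinels[j]) >= 0.2 &&
        abs(pi - pj) <= 5e5
      expect_false(linked)
    }
  }
})

test_that("locus classification follows the four-category rule table", {
  panel <- make_ld_panel(ld_block_spec(2, 3, 0.8), region_size = 3)
  # known: genome-wide significant in both traits
  expect_equal(classify_locus("rs1", 1e-9, 1e-10, "rs9", "rs9", panel), 1L)
  # single-trait-driven
  expect_equal(classify_locus("rs1", 1e-9, 1e-4, character(), character(),
                              panel), 2L)
  # LD-tagged: r2(rs1, rs2) = 0.64 > 0.2 with a trait-1 index SNP
  expect_equal(classify_locus("rs1", 1e-4, 1e-4, "rs2", character(), panel), 3L)
  # novel: only weak LD (r2(rs1, rs3) = 0.8^4 = 0.41? use rs4: r2 = 0)
  expect_equal(classify_locus("rs1", 1e-4, 1e-4, "rs4", "rs5", panel), 4L)
})

test_that("a fully null scan screens out essentially every SNP", {
  panel <- test_panel()
  hits <- vapply(1:3, function(s) {
    pair <- simulate_pair(sim_truth(m = 2000L, h2_1 = 0, h2_2 = 0,
                                    rg_true = 0), panel, seed = 300 + s)
    hp <- harmonize_pair(pair$ss1, pair$ss2)
    sc <- cpassoc_scan(hp, panel, null_reps = 5000, seed = 400 + s)
    nrow(sc$candidates)
  }, numeric(1))
  expect_equal(sum(hits), 0)
})

test_that("a planted shared signal is screened, clumped and classified", {
  panel <- test_panel()
  pair <- simulate_pair(sim_truth(m = 2000L, h2_1 = 0, h2_2 = 0, rg_true = 0),
                        panel, seed = 65)
  # plant a strong shared association at rs1000 and LD partners
  idx <- which(panel$snps$region == panel$snps$region[1000])
  Rm <- panel$R[[panel$snps$region[1000]]]
  spike <- drop(Rm[, which(idx == 1000)] * 8)
  for (tr in c("ss1", "ss2")) {
    z <- pair[[tr]]$beta / pair[[tr]]$se
    z[idx] <- z[idx] + spike
    pair[[tr]]$beta <- z * pair[[tr]]$se
    pair[[tr]]$p <- 2 * pnorm(-abs(z))
  }
  hp <- harmonize_pair(pair$ss1, pair$ss2)
  sc <- cpassoc_scan(hp, panel, null_reps = 5000, seed = 66)
  expect_gt(nrow(sc$candidates), 0)
  expect_gte(length(sc$loci), 1)
  sent <- vapply(sc$loci, `[[`, character(1), "sentinel")
  expect_true(any(sent %in% panel$snps$snp[idx]))
  expect_true(all(vapply(sc$loci, `[[`, integer(1), "category") %in% 1:4))
})
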