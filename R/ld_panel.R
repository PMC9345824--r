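#' LD reference panels
#'
#' An `ld_panel` holds a partition of the SNP set into LD-independent
#' regions, a per-region SNP correlation matrix, and the per-SNP LD scores
#' \eqn{\ell_j = \sum_k r^2_{jk}} taken over the SNP's region. Regions are
#' half-open intervals `[start, end)` on 1-based build-37 coordinates,
#' non-overlapping, and cover all SNPs present. Cross-region LD is 0 by
#' construction (the partition is LD-independent).
#'
#' @name ld_panel
NULL

new_ld_panel <- function(snps, regions, R_list) {
  stopifnot(all(snps$region >= 1L), length(R_list) == nrow(regions))
  ld <- numeric(nrow(snps))
  for (r in seq_along(R_list)) {
    idx <- which(snps$region == r)
    Rm <- R_list[[r]]
    if (length(idx) != nrow(Rm)) stopf("region %d: SNP list and LD matrix disagree", r)
    if (any(abs(Rm) > 1 + 1e-9)) stopf("region %d: LD entries outside [-1, 1]", r)
    ld[idx] <- rowSums(Rm^2)
  }
  if (any(ld < 1 - 1e-8)) stopf("LD scores below 1: self-term missing")
  snps$ld_score <- ld
  structure(list(snps = snps, regions = regions, R = R_list),
            class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("ld_panel: %d SNPs in %d regions, mean LD score %.3f\n",
              nrow(x$snps), nrow(x$regions), mean(x$snps$ld_score)))
  invisible(x)
}

#' Specification of a block-diagonal AR(1) LD structure
#'
#' A synthetic stand-in for an external haplotype reference: the genome is
#' a sequence of independent LD blocks, each with autoregressive
#' correlation `R[j,k] = rho_ar^|j-k|`.
#'
#' @param n_blocks number of LD blocks.
#' @param block_size SNPs per block.
#' @param rho_ar within-block AR(1) correlation(s), each with absolute
#'   value < 1; a vector is recycled across blocks, giving the
#'   heterogeneous LD-score spread real genomes show.
#' @return An object of class `ld_block_spec`.
#' @export
ld_block_spec <- function(n_blocks, block_size, rho_ar = 0.5) {
  if (any(abs(rho_ar) >= 1)) stopf("|rho_ar| must be < 1")
  if (n_blocks < 1 || block_size < 1) stopf("n_blocks and block_size must be >= 1")
  structure(list(n_blocks = as.integer(n_blocks),
                 block_size = as.integer(block_size),
                 rho_ar = rep_len(rho_ar, n_blocks)),
            class = "ld_block_spec")
}

#' Build a synthetic LD panel from a block specification
#'
#' SNPs are named `rs1 ... rsM`, placed on chromosome 1 at 10 kb spacing.
#' Regions tile the SNP list in groups of `region_size` SNPs;
#' `region_size` must be a multiple of `block_size` so that regions are
#' LD-independent (cross-region correlation exactly 0).
#'
#' @param spec an [ld_block_spec].
#' @param region_size SNPs per region (default: one block per region).
#' @param spacing_bp base pairs between adjacent SNPs (default 10000).
#' @return An `ld_panel`.
#' @export
make_ld_panel <- function(spec, region_size = spec$block_size,
                          spacing_bp = 10000L) {
  stopifnot(inherits(spec, "ld_block_spec"))
  m <- spec$n_blocks * spec$block_size
  if (region_size %% spec$block_size != 0 || m %% region_size != 0) {
    stopf("region_size must be a multiple of block_size and divide m")
  }
  bs <- spec$block_size
  lag <- abs(outer(seq_len(bs), seq_len(bs), "-"))
  blocks_per_region <- region_size %/% bs
  n_regions <- m %/% region_size
  region_R_for <- function(r) {
    Rm <- diag(region_size) * 0
    for (b in seq_len(blocks_per_region)) {
      idx <- (b - 1L) * bs + seq_len(bs)
      Rm[idx, idx] <- spec$rho_ar[(r - 1L) * blocks_per_region + b]^lag
    }
    Rm
  }
  pos <- as.integer(seq_len(m)) * as.integer(spacing_bp)
  snps <- data.frame(
    snp = paste0("rs", seq_len(m)), chrom = 1L, pos = pos,
    region = rep(seq_len(n_regions), each = region_size),
    stringsAsFactors = FALSE
  )
  starts <- pos[seq(1L, m, by = region_size)]
  ends <- c(starts[-1L], pos[m] + spacing_bp)
  regions <- data.frame(region = seq_len(n_regions), chrom = 1L,
                        start = starts, end = ends)
  R_list <- lapply(seq_len(n_regions), region_R_for)
  for (r in seq_len(n_regions)) {
    dimnames(R_list[[r]]) <- list(snps$snp[snps$region == r],
                                  snps$snp[snps$region == r])
  }
  new_ld_panel(snps, regions, R_list)
}

#' Pairwise LD r-squared between two SNPs in a panel
#'
#' SNPs in different regions (or absent from the panel) have r² = 0.
#'
#' @param panel an `ld_panel`.
#' @param snp_a,snp_b rsIDs.
#' @return r² in \[0, 1\].
#' @export
panel_r2 <- function(panel, snp_a, snp_b) {
  ia <- match(snp_a, panel$snps$snp)
  ib <- match(snp_b, panel$snps$snp)
  if (is.na(ia) || is.na(ib)) return(0)
  ra <- panel$snps$region[ia]
  if (ra != panel$snps$region[ib]) return(0)
  Rm <- panel$R[[ra]]
  unname(Rm[panel$snps$snp[ia], panel$snps$snp[ib]]^2)
}

#' Read per-SNP LD scores
#'
#' Whitespace-delimited file with header columns `CHR, SNP, BP, L2`.
#'
#' @param path file path.
#' @return data frame with columns `snp, chrom, pos, ld_score`.
#' @export
read_ld_scores <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("CHR", "SNP", "BP", "L2")
  if (!all(need %in% names(raw))) {
    stopf("LD-score file must have columns %s", paste(need, collapse = ", "))
  }
  data.frame(snp = as.character(raw$SNP), chrom = as.integer(raw$CHR),
             pos = as.integer(raw$BP), ld_score = as.numeric(raw$L2),
             stringsAsFactors = FALSE)
}

#' Read a genome partition from a BED-style file
#'
#' Three columns (chrom, start, end), 0-based half-open on disk, converted
#' to the package's 1-based half-open convention on read.
#'
#' @param path file path.
#' @return data frame with columns `region, chrom, start, end`.
#' @export
read_region_bed <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stopf("region file needs 3 columns (chrom, start, end)")
  chrom <- sub("^chr", "", as.character(raw[[1]]))
  data.frame(region = seq_len(nrow(raw)), chrom = as.integer(chrom),
             start = as.integer(raw[[2]]) + 1L, end = as.integer(raw[[3]]) + 1L)
}
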