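#' Transcriptome-wide association from precomputed expression weights
#'
#' For a gene with expression-weight vector w over the SNPs of its region,
#' the association between genetically predicted expression and the trait
#' is `Z = w'z / sqrt(w'Rw)` where z are the GWAS z-scores and R the
#' regional LD. FDR control is Benjamini-Hochberg within each tissue.
#'
#' @name twas
NULL

#' TWAS association z-score for one gene
#'
#' @param w named weight vector (or data frame `snp, weight`).
#' @param z named GWAS z-scores covering the weight SNPs.
#' @param R LD matrix over the same SNPs (dimnames required when subsetting
#'   by name).
#' @return list with `z_twas`, `p` (two-sided) or `NA` with a reason when
#'   the predicted-expression variance `w'Rw` is numerically zero.
#' @export
twas_z <- function(w, z, R) {
  if (is.data.frame(w)) {
    wv <- w$weight
    names(wv) <- w$snp
    w <- wv
  }
  snps <- names(w)
  if (!is.null(snps)) {
    z <- z[snps]
    R <- R[snps, snps, drop = FALSE]
  }
  denom <- drop(t(w) %*% R %*% w)
  if (denom <= 1e-12) {
    return(list(z_twas = NA_real_, p = NA_real_, reason = "zero_expression_variance"))
  }
  zt <- drop(crossprod(w, z)) / sqrt(denom)
  list(z_twas = zt, p = 2 * stats::pnorm(-abs(zt)), reason = "")
}

#' Benjamini-Hochberg adjusted FDR values
#'
#' @param p_values p-values in (0, 1].
#' @return q-values (same order as input).
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stopf("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Run a single-trait TWAS over all genes of a weight set
#'
#' @param tw weight set from [simulate_twas_weights] (or the same shape:
#'   `weights` list + `genes` map).
#' @param z named GWAS z-vector over the panel SNPs.
#' @param panel the `ld_panel` the weights were built on.
#' @param tissue tissue label attached to every row (FDR is computed
#'   within this call, i.e. within one tissue).
#' @return data frame `gene, tissue, z_twas, p, q, best_gwas_snp`, one row
#'   per gene with a defined association.
#' @export
twas_scan <- function(tw, z, panel, tissue = "tissue1") {
  rows <- lapply(seq_len(nrow(tw$genes)), function(g) {
    gene <- tw$genes$gene[g]
    region <- tw$genes$region[g]
    snps_r <- panel$snps$snp[panel$snps$region == region]
    res <- twas_z(tw$weights[[gene]], z, panel$R[[region]])
    best <- snps_r[which.max(abs(z[snps_r]))]
    data.frame(gene = gene, tissue = tissue, z_twas = res$z_twas, p = res$p,
               best_gwas_snp = best, reason = res$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  defined <- !is.na(out$p)
  out$q <- NA_real_
  out$q[defined] <- bh_fdr(out$p[defined])
  rownames(out) <- NULL
  out[, c("gene", "tissue", "z_twas", "p", "q", "best_gwas_snp", "reason")]
}

#' Intersect FDR-significant TWAS genes across two traits
#'
#' A gene is shared when it is FDR-significant (q < threshold) in at least
#' one tissue for both traits; q-values must have been computed within
#' each (trait, tissue) stratum.
#'
#' @param results1,results2 [twas_scan]-shaped data frames (possibly
#'   row-bound across tissues) for the two traits.
#' @param q_threshold FDR threshold (default 0.05).
#' @return data frame with one row per shared gene: the significant-tissue
#'   list and the TWAS z-score range per trait.
#' @export
intersect_significant <- function(results1, results2, q_threshold = 0.05) {
  sig <- function(res) res[!is.na(res$q) & res$q < q_threshold, , drop = FALSE]
  s1 <- sig(results1)
  s2 <- sig(results2)
  shared <- intersect(unique(s1$gene), unique(s2$gene))
  if (!length(shared)) {
    return(data.frame(gene = character(), tissues1 = character(),
                      tissues2 = character(), z_range1 = character(),
                      z_range2 = character(), stringsAsFactors = FALSE))
  }
  fmt <- function(res, g) {
    r <- res[res$gene == g, , drop = FALSE]
    list(tissues = paste(sort(unique(r$tissue)), collapse = ","),
         z_range = sprintf("%.3f..%.3f", min(r$z_twas), max(r$z_twas)))
  }
  rows <- lapply(shared, function(g) {
    a <- fmt(s1, g); b <- fmt(s2, g)
    data.frame(gene = g, tissues1 = a$tissues, tissues2 = b$tissues,
               z_range1 = a$z_range, z_range2 = b$z_range,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
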