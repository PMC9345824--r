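#' Published pleiotropic SNPs for type 2 diabetes / glycaemic traits and PCOS
#'
#' The sentinel SNPs reported by a published cross-trait meta-analysis of
#' type 2 diabetes, BMI-adjusted type 2 diabetes, fasting glucose, fasting
#' insulin and HbA1c (each paired with polycystic ovary syndrome): one row
#' per (trait pair, SNP), with signed effect-allele betas, single-trait
#' p-values, the cross-phenotype meta-analysis p-value, a novelty flag
#' (shared SNPs neither driven by one trait nor in LD with known index
#' SNPs) and genes within the clumping range. Bundled as a small worked
#' example for the screening and counting utilities; the z-scores implied
#' by the printed betas and p-values are recoverable with [z_from_p].
#'
#' @return data frame with columns `trait_pair, snp, chr, bp, a1, a2, eaf,
#'   beta_pcos, beta_trait, p_pcos, p_trait, p_cpassoc, novel, genes`.
#' @export
published_pleiotropic_snps <- function() {
  path <- system.file("extdata", "pleiotropic_snps_t2d_pcos.tsv",
                      package = "crosstraitr", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA", quote = "")
}
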