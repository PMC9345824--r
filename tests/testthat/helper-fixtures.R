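# Shared fixtures, built in code at test time.

# Small heterogeneous-LD panel used across modules (m = 2000).
test_panel <- function(n_blocks = 100L, block_size = 20L,
                       rho = c(0.1, 0.4, 0.7, 0.9)) {
  make_ld_panel(ld_block_spec(n_blocks, block_size, rho))
}

# Larger panel for LDSC recovery work (m = 10000).
rg_panel <- function() {
  make_ld_panel(ld_block_spec(500L, 20L, c(0.1, 0.4, 0.7, 0.9)))
}

# A tiny well-formed sumstats table.
toy_sumstats <- function(n_snp = 5L, n = 10000) {
  z <- seq(-2, 2, length.out = n_snp)
  sumstats(snp = paste0("rs", seq_len(n_snp)), chrom = 1L,
           pos = seq_len(n_snp) * 1000L, a1 = "A", a2 = "G",
           eaf = 0.3, beta = z / sqrt(n), se = 1 / sqrt(n),
           p = 2 * pnorm(-abs(z)), n = n)
}

# Write a sumstats-dialect TSV and return its path.
write_toy_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
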