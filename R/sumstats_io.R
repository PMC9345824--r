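#' GWAS summary statistics: construction, validation and I/O
#'
#' A `sumstats` object is a validated data frame with one row per SNP and
#' columns `snp`, `chrom`, `pos`, `a1` (effect allele), `a2` (other allele),
#' `eaf` (effect-allele frequency, may be `NA`), `beta`, `se`, `p`, `n`
#' and optionally `n_case`, `n_control`. Effect sizes are log-odds ratios
#' for binary traits and trait units otherwise; positions are 1-based on
#' genome build 37.
#'
#' @param snp character rsIDs, unique.
#' @param chrom integer chromosome (1-22).
#' @param pos integer base-pair position, 1-based.
#' @param a1,a2 effect / other allele, single characters in A,C,G,T.
#' @param eaf effect-allele frequency in (0,1); `NA` allowed.
#' @param beta per-allele effect size.
#' @param se standard error, positive.
#' @param p association p-value in (0,1].
#' @param n total sample size.
#' @param n_case,n_control optional case/control counts (binary traits).
#' @param validate drop rows violating the invariants (with a message)?
#' @return A data frame of class `sumstats`.
#' @export
sumstats <- function(snp, chrom, pos, a1, a2, beta, se, p, n,
                     eaf = NA_real_, n_case = NA_real_, n_control = NA_real_,
                     validate = TRUE) {
  df <- data.frame(
    snp = as.character(snp), chrom = as.integer(chrom), pos = as.integer(pos),
    a1 = toupper(as.character(a1)), a2 = toupper(as.character(a2)),
    eaf = as.numeric(eaf), beta = as.numeric(beta), se = as.numeric(se),
    p = as.numeric(p), n = as.numeric(n),
    n_case = as.numeric(n_case), n_control = as.numeric(n_control),
    stringsAsFactors = FALSE
  )
  if (validate) df <- validate_sumstats(df)
  class(df) <- c("sumstats", "data.frame")
  df
}

# Row-level invariant checks; invalid rows are dropped with a logged count.
validate_sumstats <- function(df) {
  n0 <- nrow(df)
  ok_allele <- df$a1 %in% c("A", "C", "G", "T") & df$a2 %in% c("A", "C", "G", "T") &
    df$a1 != df$a2
  ok_num <- is.finite(df$beta) & is.finite(df$se) & df$se > 0 &
    is.finite(df$p) & df$p > 0 & df$p <= 1 &
    is.finite(df$n) & df$n > 0 &
    df$chrom >= 1L & df$chrom <= 22L & df$pos >= 1L
  ok_eaf <- is.na(df$eaf) | (df$eaf > 0 & df$eaf < 1)
  # p and beta/se must agree within rounding: |dz| <= max(0.1, 5% relative)
  z_p <- z_from_p(pmin(df$p, 1), sign = 1)
  z_bs <- abs(df$beta / df$se)
  ok_z <- abs(z_p - z_bs) <= pmax(0.1, 0.05 * z_p)
  ok_z[!is.finite(ok_z)] <- FALSE
  ok_cc <- is.na(df$n_case) | is.na(df$n_control) |
    abs(df$n_case + df$n_control - df$n) <= 0.5
  keep <- ok_allele & ok_num & ok_eaf & ok_z & ok_cc
  keep[is.na(keep)] <- FALSE
  if (any(!keep)) {
    message(sprintf("validate_sumstats: dropped %d of %d rows failing invariants",
                    sum(!keep), n0))
  }
  df <- df[keep, , drop = FALSE]
  if (anyDuplicated(df$snp)) {
    dup <- duplicated(df$snp)
    message(sprintf("validate_sumstats: dropped %d duplicated snp ids", sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  if (nrow(df) == 0L) stopf("no rows survive summary-statistics validation")
  rownames(df) <- NULL
  df
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' The native dialect has header columns `SNP, CHR, BP, A1, A2, EAF, BETA,
#' SE, P, N` and optionally `N_CASE, N_CONTROL`. `column_map` renames
#' non-standard headers, e.g. `c(SNP = "rsid", P = "pval")`.
#'
#' @param path file path.
#' @param column_map named character vector mapping standard names to the
#'   file's column names.
#' @return A validated [sumstats] object; rows failing invariants are
#'   dropped with a message.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  std <- c(SNP = "SNP", CHR = "CHR", BP = "BP", A1 = "A1", A2 = "A2",
           EAF = "EAF", BETA = "BETA", SE = "SE", P = "P", N = "N",
           N_CASE = "N_CASE", N_CONTROL = "N_CONTROL")
  if (!is.null(column_map)) std[names(column_map)] <- column_map
  mandatory <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P", "N")
  missing_cols <- mandatory[!std[mandatory] %in% names(raw)]
  if (length(missing_cols)) {
    stopf("missing mandatory column(s): %s", paste(missing_cols, collapse = ", "))
  }
  getcol <- function(key, default = NA_real_) {
    if (std[[key]] %in% names(raw)) raw[[std[[key]]]] else default
  }
  sumstats(
    snp = getcol("SNP"), chrom = getcol("CHR"), pos = getcol("BP"),
    a1 = getcol("A1"), a2 = getcol("A2"), eaf = getcol("EAF"),
    beta = getcol("BETA"), se = getcol("SE"), p = getcol("P"),
    n = getcol("N"), n_case = getcol("N_CASE"), n_control = getcol("N_CONTROL")
  )
}

#' Write summary statistics in the native tab-separated dialect
#'
#' Deterministic column order, tab separators, `.` decimal mark, `NA` for
#' missing values; [read_sumstats] on the result reproduces the object.
#'
#' @param ss a [sumstats] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  out <- data.frame(SNP = ss$snp, CHR = ss$chrom, BP = ss$pos, A1 = ss$a1,
                    A2 = ss$a2, EAF = ss$eaf, BETA = ss$beta, SE = ss$se,
                    P = ss$p, N = ss$n, N_CASE = ss$n_case,
                    N_CONTROL = ss$n_control)
  write_results(out, path)
}

#' Write a result table as deterministic TSV
#'
#' Columns are written in their current order, tab-separated with a header,
#' `NA` for missing entries, no quoting and no row names, so repeated runs
#' produce byte-identical files.
#'
#' @param obj a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path) {
  ok <- tryCatch({
    utils::write.table(as.data.frame(obj), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA", dec = ".")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopf("cannot write to %s", path)
  invisible(path)
}

#' Signed z-score from a two-sided p-value
#'
#' @param p two-sided p-value(s) in (0,1].
#' @param sign sign(s) of the effect, +1 or -1 (recycled).
#' @return `sign * qnorm(1 - p/2)`.
#' @export
z_from_p <- function(p, sign = 1) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stopf("p-values must lie in (0, 1]")
  }
  sign(sign + (sign == 0)) * stats::qnorm(p / 2, lower.tail = FALSE)
}

allele_complement <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_palindromic <- function(a1, a2) {
  a2 == allele_complement(a1)
}

#' Harmonize two summary-statistics sets onto a common effect allele
#'
#' Intersects the two traits by rsID and aligns trait 2's effects to trait
#' 1's effect allele: swapped alleles flip `beta` and `eaf`; strand
#' complements are resolved by complementing before matching. Palindromic
#' SNPs (A/T, G/C) cannot be resolved by allele letters: they are aligned
#' by effect-allele frequency when both frequencies are informative, and
#' always dropped when either frequency is within
#' `palindromic_eaf_window` of 0.5 or missing. `drop_palindromic = TRUE`
#' removes them outright (strict sensitivity mode).
#'
#' @param ss1,ss2 validated [sumstats] objects.
#' @param drop_palindromic drop all palindromic SNPs?
#' @param palindromic_eaf_window half-width of the ambiguous frequency zone
#'   around 0.5 (default 0.08, i.e. eaf in \[0.42, 0.58\] is ambiguous).
#' @return A data frame of class `harmonized_pair` with per-SNP columns
#'   `snp, chrom, pos, a1, a2, eaf1, beta1, se1, p1, n1, eaf2, beta2, se2,
#'   p2, n2, palindromic`.
#' @export
harmonize_pair <- function(ss1, ss2, drop_palindromic = FALSE,
                           palindromic_eaf_window = 0.08) {
  shared <- intersect(ss1$snp, ss2$snp)
  if (length(shared) == 0L) stopf("no shared SNPs between the two traits")
  i1 <- match(shared, ss1$snp)
  i2 <- match(shared, ss2$snp)
  a1 <- ss1$a1[i1]; a2 <- ss1$a2[i1]
  b1 <- ss2$a1[i2]; b2 <- ss2$a2[i2]
  pal <- is_palindromic(a1, a2)

  same  <- b1 == a1 & b2 == a2
  swap  <- b1 == a2 & b2 == a1
  cb1 <- allele_complement(b1); cb2 <- allele_complement(b2)
  strand      <- !pal & !same & !swap & cb1 == a1 & cb2 == a2
  strand_swap <- !pal & !same & !swap & cb1 == a2 & cb2 == a1
  matched <- same | swap | strand | strand_swap
  flip <- swap | strand_swap

  eaf1 <- ss1$eaf[i1]
  eaf2 <- ss2$eaf[i2]
  beta2 <- ss2$beta[i2]
  eaf2_al <- ifelse(flip, 1 - eaf2, eaf2)
  beta2_al <- ifelse(flip, -beta2, beta2)

  keep <- matched
  if (any(pal)) {
    if (drop_palindromic) {
      keep <- keep & !pal
    } else {
      ambiguous <- pal & (
        is.na(eaf1) | is.na(eaf2) |
          abs(eaf1 - 0.5) <= palindromic_eaf_window |
          abs(eaf2 - 0.5) <= palindromic_eaf_window
      )
      keep <- keep & !ambiguous
      # frequency-based re-orientation of the unambiguous palindromic SNPs:
      # if the letter-aligned frequencies disagree on which allele is minor,
      # the two studies report opposite strands/orders, so flip once more.
      res <- pal & keep & (eaf1 - 0.5) * (eaf2_al - 0.5) < 0
      beta2_al[res] <- -beta2_al[res]
      eaf2_al[res] <- 1 - eaf2_al[res]
    }
  }
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(sprintf("harmonize_pair: dropped %d of %d shared SNPs (%d unmatched alleles, %d palindromic)",
                    n_drop, length(shared), sum(!matched), sum(!keep & matched)))
  }
  if (!any(keep)) stopf("no shared SNPs survive harmonization")

  out <- data.frame(
    snp = shared, chrom = ss1$chrom[i1], pos = ss1$pos[i1],
    a1 = a1, a2 = a2,
    eaf1 = eaf1, beta1 = ss1$beta[i1], se1 = ss1$se[i1],
    p1 = ss1$p[i1], n1 = ss1$n[i1],
    eaf2 = eaf2_al, beta2 = beta2_al, se2 = ss2$se[i2],
    p2 = ss2$p[i2], n2 = ss2$n[i2],
    palindromic = pal,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("harmonized_pair", "data.frame")
  out
}

# Split a harmonized pair back into two sumstats objects (shared alleles).
split_harmonized <- function(hp, n_case1 = NA, n_control1 = NA,
                             n_case2 = NA, n_control2 = NA) {
  list(
    ss1 = sumstats(hp$snp, hp$chrom, hp$pos, hp$a1, hp$a2, hp$beta1, hp$se1,
                   hp$p1, hp$n1, eaf = hp$eaf1, n_case = n_case1,
                   n_control = n_control1, validate = FALSE),
    ss2 = sumstats(hp$snp, hp$chrom, hp$pos, hp$a1, hp$a2, hp$beta2, hp$se2,
                   hp$p2, hp$n2, eaf = hp$eaf2, n_case = n_case2,
                   n_control = n_control2, validate = FALSE)
  )
}

#' Effective sample size of a case-control study
#'
#' @param n_case,n_control case and control counts.
#' @return `4 / (1/n_case + 1/n_control)`.
#' @export
effective_n <- function(n_case, n_control) {
  4 / (1 / n_case + 1 / n_control)
}
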