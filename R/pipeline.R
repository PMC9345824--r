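#' Orchestrate the full cross-trait workflow from one configuration
#'
#' Stage order follows the cross-trait design: overall genetic
#' correlation, local genetic correlation, cross-phenotype meta-analysis,
#' TWAS, bidirectional MR. Stages only share the harmonized inputs, so a
#' failing stage halts nothing else; the report marks it as failed.
#'
#' @name pipeline
NULL

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    k_tests = 6L,          # trait pairs in the multiplicity family
    stages = c("rg", "local", "cpassoc", "twas", "mr"),
    sim = list(),          # overrides for sim_truth()
    ld = list(n_blocks = 250L, block_size = 20L, rho_ar = 0.5,
              region_size = 20L),
    rg = list(n_blocks = 50L),
    local = list(n_null = 1000L),
    cpassoc = list(null_reps = 20000L),
    twas = list(n_genes = 50L, sparsity = 0.2, n_causal = 2L, lambda = 7),
    mr = list(p_threshold = 5e-8, clump_r2 = 0.01, clump_kb = 500,
              k_instruments = 40L)
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Unknown keys (top-level or within a stage block) are rejected;
#' defaults are injected for everything unspecified. All problems are
#' reported at once.
#'
#' @param config named list (possibly empty).
#' @return normalized config with a `warnings` attribute listing every
#'   default injected.
#' @export
validate_config <- function(config = list()) {
  defaults <- pipeline_defaults()
  problems <- character()
  warnings <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    problems <- c(problems, sprintf("unknown config key(s): %s",
                                    paste(unknown, collapse = ", ")))
  }
  for (blk in c("sim", "ld", "rg", "local", "cpassoc", "twas", "mr")) {
    if (!is.null(config[[blk]])) {
      known <- if (blk == "sim") names(formals(sim_truth)) else names(defaults[[blk]])
      bad <- setdiff(names(config[[blk]]), known)
      if (length(bad)) {
        problems <- c(problems, sprintf("unknown key(s) in `%s`: %s", blk,
                                        paste(bad, collapse = ", ")))
      }
    }
  }
  if (!is.null(config$stages)) {
    bad <- setdiff(config$stages, defaults$stages)
    if (length(bad)) {
      problems <- c(problems, sprintf("unknown stage(s): %s",
                                      paste(bad, collapse = ", ")))
    }
  }
  if (length(problems)) stopf("invalid configuration:\n- %s",
                              paste(problems, collapse = "\n- "))
  out <- defaults
  for (key in names(config)) {
    if (is.list(defaults[[key]]) && is.list(config[[key]])) {
      out[[key]][names(config[[key]])] <- config[[key]]
    } else {
      out[[key]] <- config[[key]]
    }
  }
  for (key in setdiff(names(defaults), names(config))) {
    warnings <- c(warnings, sprintf("using default for `%s`", key))
  }
  if (out$k_tests < 1) stopf("invalid configuration:\n- k_tests must be >= 1")
  attr(out, "warnings") <- warnings
  out
}

run_stage <- function(report, name, fun) {
  res <- tryCatch(list(ok = TRUE, value = fun()),
                  error = function(e) list(ok = FALSE, value = conditionMessage(e)))
  if (res$ok) {
    report$stages[[name]] <- list(status = "ok")
    report[[name]] <- res$value
  } else {
    report$stages[[name]] <- list(status = "failed", error = res$value)
    warnf("stage %s failed: %s", name, res$value)
  }
  report
}

#' Run the cross-trait pipeline on a simulated trait pair
#'
#' Generates an LD panel and a coupled pair of GWAS summary statistics
#' from the configured ground truth, then executes the enabled stages and
#' returns a report with one table per stage (overall-correlation table,
#' locus table, shared-gene table, MR forest-style table) plus provenance
#' (seed, parameters, versions). With `out_dir` set, each table is also
#' written as a deterministic TSV plus a JSON report.
#'
#' @param config configuration list (see [validate_config]).
#' @return report list of class `crosstrait_report`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  seed <- as.integer(cfg$seed)
  truth <- do.call(sim_truth, cfg$sim)
  panel <- make_ld_panel(
    ld_block_spec(cfg$ld$n_blocks, cfg$ld$block_size, cfg$ld$rho_ar),
    region_size = cfg$ld$region_size
  )
  if (nrow(panel$snps) != truth$m) {
    truth$m <- nrow(panel$snps)   # panel defines the SNP set
  }
  pair <- simulate_pair(truth, panel, seed = child_seed(seed, 1))
  hp <- harmonize_pair(pair$ss1, pair$ss2)

  report <- list(stages = list(),
                 provenance = list(
                   package = "crosstraitr",
                   version = as.character(utils::packageVersion("crosstraitr")),
                   r_version = R.version.string,
                   seed = seed,
                   truth = unclass(truth),
                   config = cfg[setdiff(names(cfg), "out_dir")]
                 ))

  if ("rg" %in% cfg$stages) {
    report <- run_stage(report, "rg", function() {
      r <- estimate_rg(pair$ss1, pair$ss2, panel, n_blocks = cfg$rg$n_blocks)
      data.frame(trait1 = "trait1", trait2 = "trait2", rg = r$rg,
                 rg_se = r$rg_se, p = r$p,
                 label = bonferroni_gate(r$p, cfg$k_tests),
                 h2_1 = r$h2_1, h2_2 = r$h2_2, gencov = r$gencov,
                 cross_intercept = r$cross_intercept, m_snps = r$m_snps)
    })
  }
  if ("local" %in% cfg$stages) {
    report <- run_stage(report, "local", function() {
      local_correlation_scan(pair$ss1, pair$ss2, panel,
                             n_null = cfg$local$n_null,
                             seed = child_seed(seed, 2))
    })
  }
  if ("cpassoc" %in% cfg$stages) {
    report <- run_stage(report, "cpassoc", function() {
      sc <- cpassoc_scan(hp, panel, null_reps = cfg$cpassoc$null_reps,
                         seed = child_seed(seed, 3))
      loci <- sc$loci
      tab <- if (length(loci)) {
        do.call(rbind, lapply(loci, function(lc) {
          data.frame(snp = lc$sentinel, chrom = lc$chrom, pos = lc$pos,
                     p_cpassoc = lc$p, p_trait1 = lc$p_trait1,
                     p_trait2 = lc$p_trait2, category = lc$category,
                     n_members = length(lc$members))
        }))
      } else {
        data.frame(snp = character(), chrom = integer(), pos = integer(),
                   p_cpassoc = numeric(), p_trait1 = numeric(),
                   p_trait2 = numeric(), category = integer(),
                   n_members = integer())
      }
      list(locus_table = tab, n_candidates = nrow(sc$candidates),
           r_matrix = sc$r_matrix)
    })
  }
  if ("twas" %in% cfg$stages) {
    report <- run_stage(report, "twas", function() {
      tw <- simulate_twas_weights(panel, cfg$twas$n_genes, cfg$twas$sparsity,
                                  cfg$twas$n_causal,
                                  seed = child_seed(seed, 4))
      z1 <- spike_twas_z(panel, tw, cfg$twas$lambda, seed = child_seed(seed, 5))
      z2 <- spike_twas_z(panel, tw, cfg$twas$lambda, seed = child_seed(seed, 6))
      res1 <- twas_scan(tw, z1, panel)
      res2 <- twas_scan(tw, z2, panel)
      list(trait1 = res1, trait2 = res2,
           shared = intersect_significant(res1, res2),
           causal_genes = tw$causal_genes)
    })
  }
  if ("mr" %in% cfg$stages) {
    report <- run_stage(report, "mr", function() {
      iv <- simulate_instruments(truth, cfg$mr$k_instruments,
                                 seed = child_seed(seed, 7))
      bundle <- mr_battery(iv, seed = child_seed(seed, 8))
      fe <- function(m) if (is.null(m) || is.null(m$estimate)) {
        c(NA_real_, NA_real_, NA_real_)
      } else c(m$estimate, m$se, m$p)
      methods <- list(ivw = bundle$ivw, egger = bundle$egger,
                      weighted_median = bundle$weighted_median)
      tab <- do.call(rbind, lapply(names(methods), function(nm) {
        v <- fe(methods[[nm]])
        data.frame(method = nm, estimate = v[1], se = v[2],
                   or = exp(v[1]), or_lower = exp(v[1] - 1.96 * v[2]),
                   or_upper = exp(v[1] + 1.96 * v[2]), p = v[3],
                   label = bonferroni_gate(v[3], cfg$k_tests))
      }))
      list(forest_table = tab, bundle = bundle)
    })
  }

  class(report) <- "crosstrait_report"
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

# Write the per-stage TSVs and a JSON report under `dir`.
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$rg)) write_results(report$rg, file.path(dir, "overall_rg.tsv"))
  if (!is.null(report$local)) write_results(report$local, file.path(dir, "local_rg.tsv"))
  if (!is.null(report$cpassoc)) {
    write_results(report$cpassoc$locus_table, file.path(dir, "pleiotropic_loci.tsv"))
  }
  if (!is.null(report$twas)) {
    write_results(report$twas$shared, file.path(dir, "shared_genes.tsv"))
  }
  if (!is.null(report$mr)) {
    write_results(report$mr$forest_table, file.path(dir, "mr_forest.tsv"))
  }
  summary <- list(
    provenance = report$provenance,
    stages = report$stages,
    rg = if (!is.null(report$rg)) report$rg,
    n_pleiotropic_loci = if (!is.null(report$cpassoc)) nrow(report$cpassoc$locus_table),
    n_shared_genes = if (!is.null(report$twas)) nrow(report$twas$shared)
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
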