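## Pipeline wiring: simulate -> qc -> metrics -> nulls -> compare (->
## structure), with a JSON run manifest recording seeds, configuration and
## per-stage counts so any output can be reproduced.

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on a simulated cohort (or
#' on files read via [read_cohort()] when `vcf`/`pheno` are given), writing
#' per-stage outputs and a JSON manifest under `out_dir`.
#'
#' Stages: `"simulate"` (or file input), `"qc"` ([apply_site_filters()]),
#' `"metrics"` ([lifecycle_metrics()]), `"nulls"` (theoretical draws plus
#' sex-label and LRS permutation metrics), `"compare"` ([compare_to_null()]
#' per metric), `"structure"` ([fit_pcs()], [gwas_of_sex()],
#' [gwas_of_lrs_by_sex()], [t_statistics()]).
#'
#' @param config a [sim_config()] (ignored when `vcf` is given).
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages to run.
#' @param vcf,pheno optional input files instead of simulation.
#' @param n_boot bootstrap replicates for comparisons.
#' @param k_pcs principal components for the structure stage.
#' @param seed integer seed driving every stochastic stage (per-stage seeds
#'   are derived from it and recorded in the manifest).
#' @param verbose log stage progress.
#' @return (invisibly) a list with the manifest and in-memory results.
#' @export
run_pipeline <- function(config = sim_config(),
                         out_dir,
                         stages = c("simulate", "qc", "metrics", "nulls",
                                    "compare"),
                         vcf = NULL, pheno = NULL, n_boot = 1000,
                         k_pcs = 20, seed = config$seed, verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[", format(Sys.time(), "%H:%M:%S"),
                                            "] ", ...)
  known <- c("simulate", "qc", "metrics", "nulls", "compare", "structure")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  seeds <- list(simulate = seed, perm_sex = seed + 1L, perm_lrs = seed + 2L,
                theoretical = seed + 3L, compare = seed + 4L)
  manifest <- list(stages = stages, seeds = seeds,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   counts = list())
  res <- list()

  if (!is.null(vcf)) {
    say("reading cohort from ", vcf)
    x <- read_cohort(vcf, pheno)
  } else if ("simulate" %in% stages) {
    say("simulating cohort (", config$preset, ", ", config$n_sites,
        " sites, ", config$n_f, "F/", config$n_m, "M)")
    config$seed <- seeds$simulate
    x <- simulate_cohort(config)
    manifest$config <- unclass(config[c("n_f", "n_m", "n_sites", "preset",
                                        "s", "selected_frac")])
  } else stop("stage 'simulate' or input files required")
  x <- filter_samples(x, verbose = verbose)
  manifest$counts$samples <- nrow(x$samples)
  manifest$counts$sites_input <- nrow(x$sites)

  if ("qc" %in% stages) {
    say("site QC")
    qc <- apply_site_filters(x, verbose = verbose)
    x <- qc$cohort
    utils::write.table(qc$qc, file.path(out_dir, "qc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$counts$sites_post_qc <- nrow(x$sites)
    res$qc <- qc$qc
  }

  if (any(c("metrics", "nulls", "compare", "structure") %in% stages)) {
    say("life-cycle metrics")
    metrics <- lifecycle_metrics(x)
    write_metric_table(metrics, file.path(out_dir, "metrics.tsv"))
    res$metrics <- metrics
    manifest$counts$sites_metrics <- nrow(metrics)
  }

  if (any(c("nulls", "compare") %in% stages)) {
    say("permutation nulls")
    perm_sex <- lifecycle_metrics(permute_sex_labels(x, seeds$perm_sex))
    perm_lrs <- lifecycle_metrics(permute_lrs_within_sex(x, seeds$perm_lrs))
    res$perm_sex <- perm_sex
    res$perm_lrs <- perm_lrs
  }

  if ("compare" %in% stages) {
    say("observed-vs-null comparisons")
    keep <- ld_prune(x)
    manifest$counts$sites_pruned <- length(keep)
    cmp <- list()
    specs <- list(
      adult = list(col = "scaled_adult", perm = "perm_sex"),
      reproductive = list(col = "scaled_reproductive", perm = "perm_lrs"),
      gametic = list(col = "scaled_gametic", perm = "perm_sex"),
      unfolded = list(col = "fst_unfolded", perm = "perm_lrs"))
    for (nm in names(specs)) {
      sp <- specs[[nm]]
      obs <- res$metrics[[sp$col]][keep]
      theo <- draw_theoretical_null(if (nm == "unfolded") "unfolded" else nm,
                                    sum(!is.na(obs)), seeds$theoretical)
      cmp[[paste0(nm, "_vs_theoretical")]] <-
        compare_to_null(obs, theo, n_boot = n_boot, seed = seeds$compare)
      cmp[[paste0(nm, "_vs_permuted")]] <-
        compare_to_null(obs, res[[sp$perm]][[sp$col]][keep],
                        n_boot = n_boot, seed = seeds$compare)
    }
    res$comparisons <- cmp
    report <- lapply(cmp, function(r) unclass(r)[c(
      "mean_observed", "mean_null", "wilcoxon_p", "ks_p", "top1_excess_pct",
      "top1_chisq_p", "bootstrap_diff", "empirical_p")])
    jsonlite::write_json(report, file.path(out_dir, "comparisons.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if ("structure" %in% stages) {
    say("structure-corrected metrics")
    keep <- ld_prune(x)
    pcs <- fit_pcs(subset_cohort(x, sites = keep), k = k_pcs)
    sexg <- gwas_of_sex(x, pcs, covariates = c("age", "centre"))
    lrsg <- gwas_of_lrs_by_sex(x, pcs, covariates = c("age", "centre"))
    rho <- between_sex_rho(lrsg$beta_f[keep], lrsg$beta_m[keep])
    ts <- t_statistics(lrsg, rho)
    pbar <- (res$metrics$p_f + res$metrics$p_m) / 2
    out <- data.frame(res$metrics[, c("chrom", "pos")],
                      l_hat = sexg$beta, l_se = sexg$se,
                      l_st = l_st(sexg$beta, pbar),
                      lrsg[, c("beta_f", "se_f", "beta_m", "se_m")],
                      ts[, c("t_signed", "t_abs", "unfolded_t")],
                      rho = rho)
    write_metric_table(out, file.path(out_dir, "structure.tsv"))
    res$structure <- out
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", out_dir)
  invisible(list(manifest = manifest, results = res))
}
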