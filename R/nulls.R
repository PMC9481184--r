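## Theoretical and permutation nulls, and the comparison battery used to
## contrast observed per-site metric distributions against them.

#' Draw a theoretical null for a metric
#'
#' Scaled adult/reproductive/gametic metrics are chi-square with 1 df under no
#' sex-differential selection; the unfolded metric is a product of two
#' independent standard normals.
#'
#' @param metric one of `"adult"`, `"reproductive"`, `"gametic"`,
#'   `"unfolded"`.
#' @param n_sites number of draws.
#' @param seed optional integer seed.
#' @return list of class `"null_model"` with `kind`, `metric`, `draws`, `seed`.
#' @export
draw_theoretical_null <- function(metric = c("adult", "reproductive",
                                             "gametic", "unfolded"),
                                  n_sites, seed = NULL) {
  metric <- match.arg(metric)
  stopifnot(n_sites >= 1)
  if (!is.null(seed)) set.seed(seed)
  draws <- if (metric == "unfolded")
    stats::rnorm(n_sites) * stats::rnorm(n_sites)
  else stats::rchisq(n_sites, df = 1)
  structure(list(kind = "theoretical", metric = metric, draws = draws,
                 seed = seed), class = "null_model")
}

#' Permute sex labels
#'
#' Randomly reassigns female/male labels among individuals, preserving the sex
#' ratio; LRS (and every other phenotype) travels with the individual. Used to
#' build empirical nulls for the adult and gametic metrics (and L_ST). Pooled
#' allele frequencies are untouched by construction.
#'
#' When building the empirical null of a structure-corrected statistic
#' (e.g. L_ST) under strong sex-biased structure, a global permutation
#' destroys the sex-ancestry association and with it the standard-error
#' structure of the regression; supplying `strata` (e.g. from
#' [sex_propensity_strata()]) permutes labels within strata instead - a
#' conditional randomisation that preserves each individual's structure
#' profile while still destroying genotype-sex association net of structure.
#'
#' @param x a [cohort()].
#' @param seed optional integer seed.
#' @param strata optional integer/factor vector (one per sample): permute
#'   within levels, preserving per-stratum sex counts.
#' @return a cohort with permuted sex labels.
#' @export
permute_sex_labels <- function(x, seed = NULL, strata = NULL) {
  stopifnot(inherits(x, "cohort"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(strata)) {
    x$samples$sex <- sample(x$samples$sex)
  } else {
    stopifnot(length(strata) == nrow(x$samples))
    for (b in unique(strata)) {
      i <- which(strata == b)
      x$samples$sex[i] <- sample(x$samples$sex[i])
    }
  }
  x
}

#' Sex-propensity strata for conditional permutation
#'
#' Bins individuals by their fitted probability of being female given the
#' principal components (a sex-propensity score), for use as `strata` in
#' [permute_sex_labels()] when structure is sex-biased.
#'
#' @param x a [cohort()].
#' @param structure a [fit_pcs()] result.
#' @param n_bins number of propensity bins (default 20).
#' @return integer vector of bin ids, one per sample.
#' @export
sex_propensity_strata <- function(x, structure, n_bins = 20) {
  stopifnot(inherits(x, "cohort"))
  y <- as.numeric(x$samples$sex == "F")
  prop <- stats::glm.fit(cbind(1, structure$pcs), y,
                         family = stats::binomial())$fitted.values
  cut(rank(prop, ties.method = "first"), breaks = n_bins, labels = FALSE)
}

#' Permute LRS within each sex
#'
#' Shuffles LRS values among individuals of the same sex, leaving sex labels
#' (and therefore adult allele frequencies) untouched. Used to build empirical
#' nulls for the reproductive and unfolded metrics (and the |t| statistics):
#' adult frequencies may still differ between sexes, but genotype-LRS
#' associations are destroyed, so only estimation error remains.
#'
#' @param x a [cohort()].
#' @param seed optional integer seed.
#' @return a cohort with permuted LRS.
#' @export
permute_lrs_within_sex <- function(x, seed = NULL) {
  stopifnot(inherits(x, "cohort"))
  if (!is.null(seed)) set.seed(seed)
  for (sx in c("F", "M")) {
    idx <- which(x$samples$sex == sx)
    x$samples$lrs[idx] <- x$samples$lrs[sample(idx)]
  }
  x
}

#' Greedy sliding-window LD pruning
#'
#' Within each window of `window_snps` consecutive sites, while any retained
#' pair has squared dosage correlation above `r2_max`, the lower-MAF member of
#' the worst pair is removed (ties broken by removing the later genomic
#' position); the window then slides by `step` sites. Missing dosages are
#' mean-imputed for the correlation. Deterministic.
#'
#' @param x a [cohort()] or a sites x samples dosage matrix.
#' @param window_snps window size in SNPs (default 50).
#' @param step slide in SNPs (default 10).
#' @param r2_max maximum retained pairwise r-squared (default 0.2).
#' @param sample_cap individuals used to estimate r-squared (evenly spaced
#'   subset; default 5000). r-squared precision ~1/sqrt(cap) is ample for a
#'   0.2 threshold.
#' @return integer vector of retained site indices (sorted).
#' @export
ld_prune <- function(x, window_snps = 50, step = 10, r2_max = 0.2,
                     sample_cap = 5000) {
  G <- if (inherits(x, "cohort")) x$genotypes else x
  n_sites <- nrow(G)
  n_samp <- ncol(G)
  if (n_sites <= 1) return(seq_len(n_sites))
  cols <- if (n_samp > sample_cap)
    unique(round(seq(1, n_samp, length.out = sample_cap))) else seq_len(n_samp)
  keep <- rep(TRUE, n_sites)
  p_site <- rowMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p_site, 1 - p_site)
  starts <- seq(1, max(1, n_sites - 1), by = step)
  for (s in starts) {
    win <- s:min(s + window_snps - 1, n_sites)
    win <- win[keep[win]]
    if (length(win) < 2) next
    M <- t(G[win, cols, drop = FALSE]) * 1.0
    ## mean-impute per site for the correlation
    for (j in seq_along(win)) {
      mj <- is.na(M[, j])
      if (any(mj)) M[mj, j] <- mean(M[, j], na.rm = TRUE)
    }
    sds <- apply(M, 2, stats::sd)
    const <- sds == 0 | is.na(sds)
    r2 <- matrix(0, length(win), length(win))
    if (sum(!const) >= 2)
      r2[!const, !const] <- suppressWarnings(stats::cor(M[, !const, drop = FALSE]))^2
    diag(r2) <- 0
    repeat {
      worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
      if (r2[worst[1], worst[2]] <= r2_max) break
      i <- win[worst[1]]; j <- win[worst[2]]
      drop_site <- if (maf[i] < maf[j]) i
      else if (maf[j] < maf[i]) j
      else max(i, j)  # tie: remove the later position
      keep[drop_site] <- FALSE
      w <- which(win == drop_site)
      r2[w, ] <- 0
      r2[, w] <- 0
    }
  }
  which(keep)
}

#' Compare observed metric values to a null
#'
#' Runs the comparison battery on an LD-pruned set of per-site values:
#' two-sample Wilcoxon rank-sum and Kolmogorov-Smirnov tests, enrichment of
#' observed values in the top 1\% of the null (relative excess and a 2-cell
#' goodness-of-fit chi-square), and a bootstrap over sites (with replacement)
#' of the observed-minus-null mean difference with percentile 95\% CI and
#' two-sided empirical p-value.
#'
#' @param observed numeric vector of per-site metric values (NAs dropped).
#' @param null a `"null_model"` or numeric vector of null values.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed optional integer seed for the bootstrap.
#' @param top_quantile tail probability of the enrichment test (default 0.01).
#' @param analytic_cut use the analytic chi-square(1) quantile instead of the
#'   null draws' empirical quantile for the tail cut (default FALSE).
#' @return list of class `"comparison_report"`.
#' @export
compare_to_null <- function(observed, null, n_boot = 1000, seed = NULL,
                            top_quantile = 0.01, analytic_cut = FALSE) {
  nulld <- if (inherits(null, "null_model")) null$draws else null
  observed <- observed[!is.na(observed)]
  nulld <- nulld[!is.na(nulld)]
  stopifnot(length(observed) > 1, length(nulld) > 1)
  if (!is.null(seed)) set.seed(seed)

  wil <- stats::wilcox.test(observed, nulld)
  ks <- suppressWarnings(stats::ks.test(observed, nulld))

  n_obs <- length(observed)
  if (n_obs >= 100) {
    cut <- if (analytic_cut) stats::qchisq(1 - top_quantile, df = 1)
    else stats::quantile(nulld, 1 - top_quantile, names = FALSE)
    k <- sum(observed > cut)
    expct <- top_quantile * n_obs
    excess_pct <- 100 * (k - expct) / expct
    chi <- (k - expct)^2 / expct +
      ((n_obs - k) - (n_obs - expct))^2 / (n_obs - expct)
    chi_p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  } else {
    warning("fewer than 100 observed sites: tail-enrichment test skipped")
    k <- NA_integer_; excess_pct <- NA_real_; chi <- NA_real_; chi_p <- NA_real_
  }

  diffs <- numeric(n_boot)
  n_null <- length(nulld)
  for (b in seq_len(n_boot)) {
    diffs[b] <- mean(observed[sample.int(n_obs, n_obs, replace = TRUE)]) -
      mean(nulld[sample.int(n_null, n_null, replace = TRUE)])
  }
  ci <- stats::quantile(diffs, c(0.025, 0.975), names = FALSE)
  emp_p <- max(2 * min(mean(diffs <= 0), mean(diffs >= 0)), 1 / n_boot)

  structure(list(
    mean_observed = mean(observed), mean_null = mean(nulld),
    wilcoxon_p = wil$p.value, ks_p = ks$p.value,
    top_tail_count = k, top_tail_expected = if (n_obs >= 100) expct else NA,
    top1_excess_pct = excess_pct, top1_chisq = chi, top1_chisq_p = chi_p,
    bootstrap_diff = mean(observed) - mean(nulld),
    ci95 = ci, empirical_p = emp_p, n_boot = n_boot,
    n_observed = n_obs, n_null = n_null), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("observed vs null comparison\n")
  cat(sprintf("  mean observed %.6g vs null %.6g (diff %.3g, 95%% CI [%.3g, %.3g], empirical p %.3g)\n",
              x$mean_observed, x$mean_null, x$bootstrap_diff,
              x$ci95[1], x$ci95[2], x$empirical_p))
  cat(sprintf("  Wilcoxon p %.3g; KS p %.3g\n", x$wilcoxon_p, x$ks_p))
  cat(sprintf("  top-1%% excess %.1f%% (chi-square %.3g, p %.3g)\n",
              x$top1_excess_pct, x$top1_chisq, x$top1_chisq_p))
  invisible(x)
}

#' Conditional tail means of the unfolded metric
#'
#' Means over the strictly negative and strictly positive values (zeros
#' excluded). For the product-normal null these converge to -2/pi and +2/pi.
#'
#' @param values numeric vector.
#' @return named numeric vector `c(mean_negative, mean_positive)`; an empty
#'   tail gives `NA`.
#' @export
tail_means_unfolded <- function(values) {
  values <- values[!is.na(values)]
  neg <- values[values < 0]
  pos <- values[values > 0]
  c(mean_negative = if (length(neg)) mean(neg) else NA_real_,
    mean_positive = if (length(pos)) mean(pos) else NA_real_)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate.
#' @param n_tests number of tests.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Upper-tail survival function of a standard product-normal
#'
#' `P(Z1 * Z2 > x)` for independent standard normals, by numerical
#' integration of the density `K0(|x|)/pi` (modified Bessel function of the
#' second kind).
#'
#' @param x non-negative quantile(s).
#' @return upper-tail probabilities.
#' @keywords internal
prodnorm_sf <- function(x) {
  one <- function(q) {
    if (q <= 0) return(0.5)
    0.5 - stats::integrate(function(t) besselK(t, 0) / pi, lower = 1e-12,
                           upper = q, rel.tol = 1e-10)$value
  }
  vapply(x, one, numeric(1))
}

#' Per-site p-values (and q-values) for scaled or unfolded metrics
#'
#' Scaled metrics get upper-tail chi-square(1) p-values; the unfolded metric
#' gets two-tailed p-values from the product-normal distribution
#' (`2 P(|Z1 Z2| >= |x|)`).
#'
#' @param values per-site metric values.
#' @param metric `"scaled"` (default) or `"unfolded"`.
#' @return data.frame with columns `p` and `q` (BH), NAs propagated.
#' @export
per_site_pvalues <- function(values, metric = c("scaled", "unfolded")) {
  metric <- match.arg(metric)
  p <- rep(NA_real_, length(values))
  ok <- !is.na(values)
  if (metric == "scaled") {
    stopifnot(all(values[ok] >= 0))
    p[ok] <- stats::pchisq(values[ok], df = 1, lower.tail = FALSE)
  } else {
    p[ok] <- pmin(1, 2 * prodnorm_sf(abs(values[ok])))
  }
  data.frame(p = p, q = bh_fdr(p))
}
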