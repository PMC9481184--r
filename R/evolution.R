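## Modes-of-evolution analyses: metric-MAF associations with bootstrap
## observed-vs-null contrasts, between-population F_ST, and association tests
## against user-supplied balancing-selection annotations (allele ages,
## external-population frequencies, windowed Tajima's D, candidate flags).

assoc_result <- function(estimate, se = NA_real_, p = NA_real_, n = NA_integer_,
                         model = NA_character_, ...) {
  structure(c(list(estimate = estimate, se = se, p = p, n = n, model = model),
              list(...)), class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("association (%s): estimate %.4g", x$model, x$estimate))
  if (!is.na(x$se)) cat(sprintf(" (SE %.3g)", x$se))
  if (!is.na(x$p)) cat(sprintf(", p %.3g", x$p))
  cat(sprintf(", n %d\n", x$n))
  if (!is.null(x$contrast))
    cat(sprintf("  obs - null contrast %.4g, 95%% CI [%.4g, %.4g], empirical p %.3g\n",
                x$contrast, x$contrast_ci[1], x$contrast_ci[2],
                x$contrast_p))
  invisible(x)
}

#' Metric-MAF Spearman correlation with observed-vs-null bootstrap contrast
#'
#' Rank correlation between a per-site metric and MAF, plus (when null metric
#' values are supplied) a bootstrap over sites of the difference between the
#' observed and null correlations, with percentile 95\% CI and two-sided
#' empirical p-value. Under no sex-differential selection the metrics are
#' independent of MAF, so the correlation and the contrast centre on zero.
#'
#' @param metric per-site metric values.
#' @param maf per-site minor allele frequencies.
#' @param null_metric optional per-site null metric values (same sites).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed optional integer seed.
#' @return an `assoc_result` (fields `contrast`, `contrast_ci`, `contrast_p`
#'   present when `null_metric` given).
#' @export
maf_association <- function(metric, maf, null_metric = NULL, n_boot = 1000,
                            seed = NULL) {
  ok <- !is.na(metric) & !is.na(maf)
  if (!is.null(null_metric)) ok <- ok & !is.na(null_metric)
  m <- metric[ok]; f <- maf[ok]
  if (length(unique(m)) < 2 || length(unique(f)) < 2)
    return(assoc_result(NA_real_, n = sum(ok), model = "spearman"))
  ct <- suppressWarnings(stats::cor.test(m, f, method = "spearman"))
  res <- assoc_result(unname(ct$estimate), p = ct$p.value, n = sum(ok),
                      model = "spearman")
  if (!is.null(null_metric)) {
    nm <- null_metric[ok]
    if (!is.null(seed)) set.seed(seed)
    n <- length(m)
    d <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      i <- sample.int(n, n, replace = TRUE)
      d[b] <- stats::cor(m[i], f[i], method = "spearman") -
        stats::cor(nm[i], f[i], method = "spearman")
    }
    res$contrast <- stats::cor(m, f, method = "spearman") -
      stats::cor(nm, f, method = "spearman")
    res$contrast_ci <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
    res$contrast_p <- max(2 * min(mean(d <= 0), mean(d >= 0)), 1 / n_boot)
  }
  res
}

#' Between-population F_ST
#'
#' `(p1 - p2)^2 / (4 p_bar (1 - p_bar))` with `p_bar = (p1 + p2)/2` - the
#' same kernel as adult between-sex F_ST applied to two population
#' frequencies.
#'
#' @param p1,p2 allele frequency vectors.
#' @return numeric vector; `NA` where `p_bar` is 0 or 1.
#' @export
between_pop_fst <- function(p1, p2) {
  fst_adult(p1, p2)
}

#' Frequency-adjusted allele-age association
#'
#' Spearman correlation between a metric and allele age after removing the
#' age-frequency confound (older alleles tend to be commoner). Adjustment is
#' either centring age within `n_bins` quantile bins of the local ALT
#' frequency (default, mirroring quantile-bin averaging) or taking residuals
#' of rank(age) on rank(frequency).
#'
#' @param metric per-site metric values.
#' @param allele_age per-site ages (positive; generations or years).
#' @param alt_freq_local per-site ALT-allele frequency in the analysed cohort.
#' @param method `"bin"` (default) or `"residual"`.
#' @param n_bins number of frequency bins for `"bin"` (default 20).
#' @param min_pairs minimum complete cases (default 100).
#' @return an `assoc_result`.
#' @export
age_association <- function(metric, allele_age, alt_freq_local,
                            method = c("bin", "residual"), n_bins = 20,
                            min_pairs = 100) {
  method <- match.arg(method)
  ok <- !is.na(metric) & !is.na(allele_age) & !is.na(alt_freq_local)
  if (sum(ok) < min_pairs)
    stop("need at least ", min_pairs, " complete metric/age/frequency triples")
  m <- metric[ok]; age <- allele_age[ok]; fq <- alt_freq_local[ok]
  stopifnot(all(age > 0))
  if (length(unique(m)) < 2)
    return(assoc_result(NA_real_, n = sum(ok), model = "spearman"))
  adj <- if (method == "bin") {
    bins <- cut(rank(fq, ties.method = "first"),
                breaks = n_bins, labels = FALSE)
    stats::ave(age, bins, FUN = function(z) z - mean(z))
  } else {
    stats::resid(stats::lm(rank(age) ~ rank(fq)))
  }
  ct <- suppressWarnings(stats::cor.test(m, adj, method = "spearman"))
  assoc_result(unname(ct$estimate), p = ct$p.value, n = sum(ok),
               model = "spearman")
}

#' Linear regression of a diversity response on a metric with MAF covariate
#'
#' OLS of `response ~ metric + maf`. For a between-population F_ST response
#' set `log_response = TRUE`: zero responses are dropped (with a message)
#' before the natural-log transform. For windowed responses such as Tajima's D
#' supply `pos`: metric and MAF are averaged within half-open windows
#' `[k*window, (k+1)*window)` per chromosome before the regression.
#'
#' @param response per-site (or per-window) response values.
#' @param metric,maf per-site values.
#' @param log_response natural-log-transform the response first.
#' @param pos optional per-site positions to trigger window averaging.
#' @param chrom optional per-site chromosome labels (with `pos`).
#' @param window window width in bp (default 10000).
#' @return an `assoc_result` for the metric coefficient.
#' @export
annotation_regression <- function(response, metric, maf, log_response = FALSE,
                                  pos = NULL, chrom = NULL, window = 10000) {
  ok <- !is.na(response) & !is.na(metric) & !is.na(maf)
  response <- response[ok]; metric <- metric[ok]; maf <- maf[ok]
  if (!is.null(pos)) pos <- pos[ok]
  if (!is.null(chrom)) chrom <- chrom[ok]
  if (log_response) {
    zero <- response <= 0
    if (any(zero)) {
      message(sum(zero), " non-positive response value(s) dropped before log")
      response <- response[!zero]; metric <- metric[!zero]; maf <- maf[!zero]
      if (!is.null(pos)) pos <- pos[!zero]
      if (!is.null(chrom)) chrom <- chrom[!zero]
    }
    response <- log(response)
  }
  if (!is.null(pos)) {
    key <- paste(if (is.null(chrom)) "1" else chrom, pos %/% window)
    response <- tapply(response, key, mean)
    metric <- tapply(metric, key, mean)[names(response)]
    maf <- tapply(maf, key, mean)[names(response)]
  }
  if (length(response) < 3) stop("insufficient data for regression")
  fit <- stats::lm(response ~ metric + maf)
  co <- summary(fit)$coefficients
  assoc_result(co["metric", 1], se = co["metric", 2], p = co["metric", 4],
               n = length(response), model = "linear+maf")
}

#' Logistic regression of candidate status on a metric with MAF covariate
#'
#' `candidate_flag ~ metric + maf` (binomial); reports the metric log-odds
#' coefficient. Both classes must be present; separation or non-convergence
#' gives an `NA` estimate with a reason.
#'
#' @param candidate_flag logical per-site candidate status.
#' @param metric,maf per-site values.
#' @return an `assoc_result`.
#' @export
candidate_logistic <- function(candidate_flag, metric, maf) {
  ok <- !is.na(candidate_flag) & !is.na(metric) & !is.na(maf)
  y <- as.logical(candidate_flag[ok]); m <- metric[ok]; f <- maf[ok]
  if (length(unique(y)) < 2)
    stop("candidate_flag must contain both classes")
  fit <- suppressWarnings(stats::glm(y ~ m + f, family = stats::binomial()))
  co <- summary(fit)$coefficients
  if (!fit$converged || co["m", 2] > 100)
    return(assoc_result(NA_real_, n = sum(ok), model = "logistic+maf",
                        reason = "separation or non-convergence"))
  assoc_result(co["m", 1], se = co["m", 2], p = co["m", 4], n = sum(ok),
               model = "logistic+maf")
}
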