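## Site-level quality control: standard biobank thresholds (MAF, missingness,
## exact HWE, imputation INFO) plus three artefact tests targeting read
## mis-mapping to the sex chromosomes: bounded excess heterozygosity,
## minor-allele-homozygote deficit, and sex-differential missingness, each with
## Benjamini-Hochberg FDR control across sites.

#' Artefact-filter parameters
#'
#' @param s_max strongest sex-specific selection coefficient deemed plausible
#'   (`max(s_m, s_f)`); the excess-heterozygosity bound allows for the
#'   heterozygote excess that sexually antagonistic selection of this strength
#'   could generate at a polymorphic equilibrium. Default 0.2.
#' @param alpha_q FDR level for all three artefact tests (default 0.05).
#' @return list of class `"sa_filter_params"`.
#' @export
sa_filter_params <- function(s_max = 0.2, alpha_q = 0.05) {
  stopifnot(s_max > 0, s_max < 1, alpha_q > 0, alpha_q < 1)
  structure(list(s_max = s_max, alpha_q = alpha_q), class = "sa_filter_params")
}

#' Expected F_IS under strong sexually antagonistic selection
#'
#' At a polymorphic SA equilibrium, F_IS (heterozygote-excess-positive
#' convention) is approximately normal with mean
#' `1/(2n) + p(1-p)/4 * (s_max / (1 - p s_max))^2` and variance `1/n`,
#' where `n` is the total adult count and `p` the minor allele frequency.
#'
#' @param n total adult sample size (vector ok).
#' @param p minor allele frequency in (0, 1).
#' @param params a [sa_filter_params()].
#' @return list with vectors `mean` and `variance`.
#' @export
expected_fis_under_sa <- function(n, p, params = sa_filter_params()) {
  stopifnot(all(n >= 1), all(p > 0 & p < 1, na.rm = TRUE))
  s <- params$s_max
  if (any(p * s >= 1, na.rm = TRUE)) stop("p * s_max must be < 1")
  list(mean = 1 / (2 * n) + p * (1 - p) / 4 * (s / (1 - p * s))^2,
       variance = 1 / n)
}

#' One-tailed Z-test for excess heterozygosity
#'
#' Compares observed F_IS against its expectation under strong SA selection;
#' `z = (F_IS - E[F_IS]) / sqrt(1/n)`, upper-tail standard-normal p-value.
#' Sites monomorphic in the tested group give `NA`.
#'
#' @param fis_hat observed F_IS ([estimate_fis()] convention).
#' @param n group sample size (genotyped individuals).
#' @param p group minor allele frequency.
#' @param params a [sa_filter_params()].
#' @return vector of upper-tail p-values.
#' @export
het_excess_test <- function(fis_hat, n, p, params = sa_filter_params()) {
  ok <- !is.na(fis_hat) & !is.na(p) & p > 0 & p < 1 & n >= 1
  out <- rep(NA_real_, length(fis_hat))
  if (any(ok)) {
    e <- expected_fis_under_sa(n[ok], p[ok], params)
    z <- (fis_hat[ok] - e$mean) / sqrt(e$variance)
    out[ok] <- stats::pnorm(z, lower.tail = FALSE)
  }
  out
}

#' One-tailed binomial test for a deficit of minor-allele homozygotes
#'
#' Lower-tail binomial p-value `P(X <= k | n, p^2)` comparing the observed
#' count of minor-allele homozygotes `k` among `n` genotyped individuals to
#' the Hardy-Weinberg expectation `p^2`.
#'
#' @param k observed minor-allele homozygote count (vector).
#' @param n genotyped individuals (vector).
#' @param p minor allele frequency (vector).
#' @return vector of lower-tail p-values.
#' @export
hom_deficit_test <- function(k, n, p) {
  stopifnot(all(k >= 0 & k <= n, na.rm = TRUE))
  out <- rep(NA_real_, length(k))
  ok <- !is.na(k) & !is.na(n) & !is.na(p) & n > 0
  out[ok] <- stats::pbinom(k[ok], n[ok], p[ok]^2)
  out
}

#' Chi-square test for sex-differential missingness
#'
#' 2x2 chi-square test (no continuity correction by default) on
#' missing/called counts in females vs males. A zero row or column margin
#' gives `NA`; a table with identical missing rates gives statistic 0, p = 1.
#'
#' @param missing_f,called_f,missing_m,called_m count vectors.
#' @param correct apply Yates continuity correction (default FALSE;
#'   large-sample setting).
#' @return vector of p-values.
#' @export
missing_diff_test <- function(missing_f, called_f, missing_m, called_m,
                              correct = FALSE) {
  a <- missing_f; b <- called_f; c_ <- missing_m; d <- called_m
  n <- a + b + c_ + d
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  out <- rep(NA_real_, length(a))
  ok <- !is.na(n) & r1 > 0 & r2 > 0 & c2 > 0
  zero_missing <- ok & c1 == 0
  out[zero_missing] <- 1
  go <- ok & c1 > 0
  if (any(go)) {
    e_a <- r1 * c1 / n; e_b <- r1 * c2 / n
    e_c <- r2 * c1 / n; e_d <- r2 * c2 / n
    dev <- abs(a - e_a)
    if (correct) dev <- pmax(dev - 0.5, 0)
    stat <- dev^2 / e_a + dev^2 / e_b + dev^2 / e_c + dev^2 / e_d
    out[go] <- stats::pchisq(stat[go], df = 1, lower.tail = FALSE)
  }
  out
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up BH adjustment; `NA` p-values are passed through and do not
#' count towards the number of tests. Output order follows the input.
#'
#' @param pvalues numeric vector in `[0, 1]` (NAs allowed).
#' @return vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  stats::p.adjust(pvalues, method = "BH")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact (Wigginton-style) HWE test on genotype counts, summing the
#' probabilities of all heterozygote configurations no more probable than the
#' observed one, conditional on allele counts. Mid-p is not used.
#'
#' @param n_het heterozygote count(s).
#' @param n_hom_r rare (minor)-allele homozygote count(s).
#' @param n_hom_c common-allele homozygote count(s).
#' @return vector of p-values; monomorphic sites give 1.
#' @export
hwe_exact_test <- function(n_het, n_hom_r, n_hom_c) {
  f <- function(het, homr, homc) {
    if (homr > homc) { tmp <- homr; homr <- homc; homc <- tmp }
    n <- het + homr + homc
    rare <- 2 * homr + het
    if (n == 0 || rare == 0 || rare == 2 * n) return(1)
    ## heterozygote counts share the parity of the rare-allele count
    hets <- seq.int(rare %% 2, min(rare, 2 * n - rare), by = 2)
    hr <- (rare - hets) / 2
    hc <- n - hets - hr
    ## log-probabilities up to a shared constant
    lp <- hets * log(2) - lgamma(hets + 1) - lgamma(hr + 1) - lgamma(hc + 1)
    pr <- exp(lp - max(lp))
    pr <- pr / sum(pr)
    min(1, sum(pr[pr <= pr[match(het, hets)] * (1 + 1e-12)]))
  }
  mapply(f, n_het, n_hom_r, n_hom_c)
}

#' Apply site-level quality and artefact filters
#'
#' Removes sites that are monomorphic or fail any of: MAF below `maf_min`,
#' missing rate above `miss_max`, exact HWE p-value below `hwe_min`,
#' imputation INFO score at or below `info_min`, or an FDR q-value below
#' `params$alpha_q` in an artefact test. The excess-heterozygosity and
#' minor-homozygote-deficit tests are run in three groups (combined, females,
#' males) and BH-corrected across sites separately per test and group; a site
#' fails if flagged in any group.
#'
#' @param x a [cohort()].
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param miss_max maximum missing rate (default 0.05).
#' @param hwe_min minimum exact HWE p-value (default 1e-6).
#' @param info_min INFO score threshold, sites with `info <= info_min` are
#'   removed (default 0.8).
#' @param params a [sa_filter_params()].
#' @param require_info drop sites with a missing INFO score (default FALSE:
#'   such sites are retained).
#' @param verbose log per-rule removal counts.
#' @return list with elements `cohort` (filtered) and `qc` (one row per input
#'   site: statistics, p/q-values, `pass`, semicolon-separated `reasons`).
#' @export
apply_site_filters <- function(x, maf_min = 0.01, miss_max = 0.05,
                               hwe_min = 1e-6, info_min = 0.8,
                               params = sa_filter_params(),
                               require_info = FALSE, verbose = TRUE) {
  stopifnot(inherits(x, "cohort"))
  counts <- site_counts(x)
  n_sites <- nrow(counts)

  ## combined-group genotype counts
  n2 <- counts$f_n2 + counts$m_n2
  n1 <- counts$f_n1 + counts$m_n1
  n0 <- counts$f_n0 + counts$m_n0
  n <- n2 + n1 + n0
  miss <- counts$f_miss + counts$m_miss
  p_alt <- ifelse(n > 0, (2 * n2 + n1) / (2 * n), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  miss_rate <- miss / (n + miss)

  ## minor-allele orientation per group
  minor_is_alt <- !is.na(p_alt) & p_alt <= 0.5
  grp <- list(
    combined = list(n2 = n2, n1 = n1, n0 = n0, n = n),
    female = list(n2 = counts$f_n2, n1 = counts$f_n1, n0 = counts$f_n0,
                  n = counts$f_n),
    male = list(n2 = counts$m_n2, n1 = counts$m_n1, n0 = counts$m_n0,
                n = counts$m_n))

  qc <- data.frame(maf = maf, missing_rate = miss_rate)
  qc$hwe_p <- hwe_exact_test(n1, pmin(n2, n0), pmax(n2, n0))
  qc$hwe_p[n == 0] <- NA_real_
  qc$info_score <- if ("info_score" %in% names(x$sites))
    x$sites$info_score else NA_real_

  for (g in names(grp)) {
    gg <- grp[[g]]
    p_g <- ifelse(gg$n > 0, (2 * gg$n2 + gg$n1) / (2 * gg$n), NA_real_)
    maf_g <- pmin(p_g, 1 - p_g)
    fis_g <- estimate_fis(gg$n1 / gg$n, p_g)
    k_minor <- ifelse(minor_is_alt, gg$n2, gg$n0)
    qc[[paste0("fis_", g)]] <- fis_g
    qc[[paste0("het_excess_p_", g)]] <-
      het_excess_test(fis_g, gg$n, maf_g, params)
    qc[[paste0("het_excess_q_", g)]] <- bh_fdr(qc[[paste0("het_excess_p_", g)]])
    qc[[paste0("hom_deficit_p_", g)]] <- hom_deficit_test(k_minor, gg$n, maf_g)
    qc[[paste0("hom_deficit_q_", g)]] <- bh_fdr(qc[[paste0("hom_deficit_p_", g)]])
  }

  qc$missing_diff_p <- missing_diff_test(counts$f_miss,
                                         counts$f_n, counts$m_miss, counts$m_n)
  qc$missing_diff_q <- bh_fdr(qc$missing_diff_p)

  alpha <- params$alpha_q
  fail <- list(
    maf = is.na(qc$maf) | qc$maf < maf_min,
    missing = qc$missing_rate > miss_max,
    hwe = !is.na(qc$hwe_p) & qc$hwe_p < hwe_min,
    info = if (require_info)
      is.na(qc$info_score) | qc$info_score <= info_min
    else !is.na(qc$info_score) & qc$info_score <= info_min,
    het_excess = (!is.na(qc$het_excess_q_combined) & qc$het_excess_q_combined < alpha) |
      (!is.na(qc$het_excess_q_female) & qc$het_excess_q_female < alpha) |
      (!is.na(qc$het_excess_q_male) & qc$het_excess_q_male < alpha),
    hom_deficit = (!is.na(qc$hom_deficit_q_combined) & qc$hom_deficit_q_combined < alpha) |
      (!is.na(qc$hom_deficit_q_female) & qc$hom_deficit_q_female < alpha) |
      (!is.na(qc$hom_deficit_q_male) & qc$hom_deficit_q_male < alpha),
    missing_diff = !is.na(qc$missing_diff_q) & qc$missing_diff_q < alpha)

  reasons <- character(n_sites)
  for (rule in names(fail)) {
    hit <- fail[[rule]]
    reasons[hit] <- ifelse(reasons[hit] == "", rule,
                           paste(reasons[hit], rule, sep = ";"))
  }
  qc$pass <- reasons == ""
  qc$reasons <- reasons
  if (verbose) {
    tallies <- vapply(fail, sum, integer(1))
    message("apply_site_filters: retained ", sum(qc$pass), "/", n_sites,
            " sites (", paste(names(tallies), tallies, sep = "=",
                              collapse = ", "), ")")
  }
  list(cohort = subset_cohort(x, sites = which(qc$pass)), qc = qc)
}
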