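## Life-cycle between-sex F_ST metrics.
##
## Per site and sex s we track the adult ALT-allele frequency p_s, the
## LRS-projected gametic frequency p_s', per-sex LRS moments (mu, sigma^2) and
## the heterozygosity-based F_IS, all computed over the individuals genotyped
## at that site so that per-site null multipliers honour missingness.

#' Per-site, per-sex genotype counts and LRS statistics
#'
#' Computes, for every site and each sex, genotype-class counts (`n2`, `n1`,
#' `n0` = ALT-hom, het, REF-hom), genotype-class LRS totals (`S2`, `S1`, `S0`),
#' missing-genotype counts, and LRS moments (mean and unbiased variance) over
#' the genotyped individuals. Everything downstream (frequencies, metrics,
#' scaling) derives from this table.
#'
#' @param x a [cohort()].
#' @param block number of sites per processing block (memory/speed trade-off).
#' @return data.frame with one row per site; column prefixes `f_`/`m_`.
#' @export
site_counts <- function(x, block = 512L) {
  stopifnot(inherits(x, "cohort"))
  G <- x$genotypes
  n_sites <- nrow(G)
  out <- vector("list", 2)
  names(out) <- c("f", "m")
  for (sx in c("f", "m")) {
    cols <- which(x$samples$sex == toupper(sx))
    lrs <- as.numeric(x$samples$lrs[cols])
    n_cols <- length(cols)
    res <- matrix(0, n_sites, 10)
    colnames(res) <- c("n2", "n1", "n0", "miss", "S2", "S1", "S0",
                       "n", "mu", "sigma2")
    lrs2 <- lrs^2
    for (start in seq(1L, n_sites, by = block)) {
      idx <- start:min(start + block - 1L, n_sites)
      g <- G[idx, cols, drop = FALSE]
      na <- is.na(g)
      i2 <- (!na) & g == 2L
      i1 <- (!na) & g == 1L
      i0 <- (!na) & g == 0L
      res[idx, "n2"] <- rowSums(i2)
      res[idx, "n1"] <- rowSums(i1)
      res[idx, "n0"] <- rowSums(i0)
      res[idx, "miss"] <- rowSums(na)
      res[idx, "S2"] <- i2 %*% lrs
      res[idx, "S1"] <- i1 %*% lrs
      res[idx, "S0"] <- i0 %*% lrs
      obs <- !na
      n_i <- res[idx, "n2"] + res[idx, "n1"] + res[idx, "n0"]
      s1 <- obs %*% lrs
      s2 <- obs %*% lrs2
      mu <- ifelse(n_i > 0, s1 / n_i, NA_real_)
      v <- ifelse(n_i > 1, (s2 - n_i * mu^2) / (n_i - 1), NA_real_)
      res[idx, "n"] <- n_i
      res[idx, "mu"] <- mu
      res[idx, "sigma2"] <- pmax(v, 0)
    }
    out[[sx]] <- res
  }
  df <- data.frame(out$f, out$m)
  names(df) <- c(paste0("f_", colnames(out$f)), paste0("m_", colnames(out$m)))
  df
}

#' Adult ALT-allele frequencies by sex
#'
#' `p_s = (2 n2 + n1) / (2 N_s)` per sex; `NA` when a sex has no genotyped
#' adults at the site. Vectorised over sites.
#'
#' @param counts data.frame from [site_counts()].
#' @return data.frame with columns `p_f`, `p_m`.
#' @export
adult_frequencies <- function(counts) {
  pf <- ifelse(counts$f_n > 0, (2 * counts$f_n2 + counts$f_n1) / (2 * counts$f_n),
               NA_real_)
  pm <- ifelse(counts$m_n > 0, (2 * counts$m_n2 + counts$m_n1) / (2 * counts$m_n),
               NA_real_)
  data.frame(p_f = pf, p_m = pm)
}

#' Projected gametic ALT-allele frequencies by sex
#'
#' `p_s' = (S2 + S1/2) / (S2 + S1 + S0)` where `S_g` is the cumulative LRS of
#' individuals of sex `s` with genotype class `g`. A sex with zero total LRS at
#' the site gets `NA` (the site then drops out of the reproductive/gametic
#' metrics).
#'
#' @param counts data.frame from [site_counts()].
#' @return data.frame with columns `p_f_prime`, `p_m_prime`.
#' @export
project_gametic_frequencies <- function(counts) {
  tf <- counts$f_S2 + counts$f_S1 + counts$f_S0
  tm <- counts$m_S2 + counts$m_S1 + counts$m_S0
  data.frame(
    p_f_prime = ifelse(tf > 0, (counts$f_S2 + counts$f_S1 / 2) / tf, NA_real_),
    p_m_prime = ifelse(tm > 0, (counts$m_S2 + counts$m_S1 / 2) / tm, NA_real_))
}

#' Adult between-sex F_ST
#'
#' `(p_f - p_m)^2 / (4 p_bar (1 - p_bar))` with `p_bar = (p_f + p_m)/2`;
#' `NA` when `p_bar` is 0 or 1 (monomorphic).
#'
#' @param p_f,p_m adult allele frequencies (vectors).
#' @return numeric vector.
#' @export
fst_adult <- function(p_f, p_m) {
  pbar <- (p_f + p_m) / 2
  den <- 4 * pbar * (1 - pbar)
  ifelse(is.na(den) | den <= 0, NA_real_, (p_f - p_m)^2 / den)
}

#' Reproductive between-sex F_ST
#'
#' Squared difference of the sexes' within-generation frequency changes,
#' `((p_f' - p_f) - (p_m' - p_m))^2 / (4 p_bar (1 - p_bar))`.
#'
#' @param p_f,p_m adult frequencies; `p_f_prime`,`p_m_prime` gametic
#'   projections.
#' @param p_f_prime,p_m_prime projected gametic frequencies.
#' @return numeric vector.
#' @export
fst_reproductive <- function(p_f, p_m, p_f_prime, p_m_prime) {
  pbar <- (p_f + p_m) / 2
  den <- 4 * pbar * (1 - pbar)
  num <- ((p_f_prime - p_f) - (p_m_prime - p_m))^2
  ifelse(is.na(den) | den <= 0, NA_real_, num / den)
}

#' Gametic between-sex F_ST
#'
#' Adult-style F_ST applied to the projected gametic frequencies:
#' `(p_f' - p_m')^2 / (4 p_bar' (1 - p_bar'))`.
#'
#' @param p_f_prime,p_m_prime projected gametic frequencies.
#' @return numeric vector.
#' @export
fst_gametic <- function(p_f_prime, p_m_prime) {
  fst_adult(p_f_prime, p_m_prime)
}

#' Heterozygosity-based F_IS (heterozygote-excess-positive convention)
#'
#' `P_het / (2 p (1-p)) - 1`. Note the sign convention: a heterozygote
#' *excess* gives a *positive* value (the opposite of Wright's convention).
#'
#' @param het_freq observed heterozygote frequency `P_het`.
#' @param mean_freq allele frequency `p` (any allele; the expression is
#'   symmetric in `p` and `1-p`).
#' @return numeric vector; `NA` where `p` is 0 or 1.
#' @export
estimate_fis <- function(het_freq, mean_freq) {
  den <- 2 * mean_freq * (1 - mean_freq)
  ifelse(is.na(den) | den <= 0, NA_real_, het_freq / den - 1)
}

#' Per-sex LRS moments over genotyped individuals
#'
#' Convenience accessor pulling mean, unbiased variance and count of LRS per
#' sex per site out of a [site_counts()] table.
#'
#' @param counts data.frame from [site_counts()].
#' @return data.frame `mu_f, sigma2_f, n_f, mu_m, sigma2_m, n_m`; a sex with
#'   fewer than two genotyped individuals gets `NA` moments.
#' @export
lrs_moments <- function(counts) {
  data.frame(
    mu_f = ifelse(counts$f_n >= 2, counts$f_mu, NA_real_),
    sigma2_f = ifelse(counts$f_n >= 2, counts$f_sigma2, NA_real_),
    n_f = counts$f_n,
    mu_m = ifelse(counts$m_n >= 2, counts$m_mu, NA_real_),
    sigma2_m = ifelse(counts$m_n >= 2, counts$m_sigma2, NA_real_),
    n_m = counts$m_n)
}

## Per-sex sampling SD of the within-generation frequency change
## (p_s' - p_s): sqrt[ p(1-p)/(2N) * (sigma^2/mu^2) * (1 - F_IS) ].
delta_se <- function(p, n, mu, sigma2, fis) {
  v <- p * (1 - p) / (2 * n) * (sigma2 / mu^2) * (1 - fis)
  ifelse(is.na(v) | v <= 0 | mu <= 0 | sigma2 <= 0, NA_real_, sqrt(v))
}

#' Unfolded reproductive F_ST
#'
#' The signed product of the sexes' standardised within-generation frequency
#' changes, `z_m * z_f` with
#' `z_s = (p_s' - p_s) / sqrt(p_s(1-p_s)/(2 N_s) * (sigma_s^2/mu_s^2) * (1 - F_IS_s))`.
#' Negative values are SA-like (opposing sex-specific effects on LRS),
#' positive values SC-like. Under no selection on LRS the metric is
#' distributed as a product of two independent standard normals.
#'
#' @param p_f,p_m adult frequencies.
#' @param p_f_prime,p_m_prime projected gametic frequencies.
#' @param n_f,n_m per-site genotyped adults per sex.
#' @param mu_f,mu_m,sigma2_f,sigma2_m per-site LRS moments per sex.
#' @param fis_f,fis_m per-site per-sex F_IS ([estimate_fis()] convention).
#' @return numeric vector; `NA` where a z denominator is undefined.
#' @export
fst_unfolded <- function(p_f, p_m, p_f_prime, p_m_prime, n_f, n_m,
                         mu_f, mu_m, sigma2_f, sigma2_m, fis_f, fis_m) {
  zf <- (p_f_prime - p_f) / delta_se(p_f, n_f, mu_f, sigma2_f, fis_f)
  zm <- (p_m_prime - p_m) / delta_se(p_m, n_m, mu_m, sigma2_m, fis_m)
  zm * zf
}

#' Scale F_ST metrics by their per-site null multipliers
#'
#' Divides each squared metric by the per-site multiplier of its theoretical
#' null so the scaled value is distributed chi-square with 1 df in the absence
#' of sex-differential selection:
#' \itemize{
#'   \item adult: `1/(8 N_f) + 1/(8 N_m)`
#'   \item reproductive: `sum_s p_s(1-p_s)/(2 N_s) (sigma_s^2/mu_s^2)(1-F_IS_s)`
#'     applied to `4 p_bar(1-p_bar) * F_ST`
#'   \item gametic: `sum_s (1/(8 N_s)) (1 + sigma_s^2/mu_s^2)`
#' }
#' The unfolded metric needs no scaling (its definition is already
#' standardised).
#'
#' @param metrics data.frame as built by [lifecycle_metrics()] (needs the
#'   frequency, moment and F_IS columns).
#' @return `metrics` with `scaled_adult`, `scaled_reproductive`,
#'   `scaled_gametic` columns added; undefined multipliers give `NA`.
#' @export
scale_to_null <- function(metrics) {
  m <- metrics
  mult_a <- 1 / (8 * m$n_f) + 1 / (8 * m$n_m)
  mult_a[!is.finite(mult_a) | mult_a <= 0] <- NA_real_
  m$scaled_adult <- m$fst_adult / mult_a

  vf <- delta_se(m$p_f, m$n_f, m$mu_f, m$sigma2_f, m$fis_f)^2
  vm <- delta_se(m$p_m, m$n_m, m$mu_m, m$sigma2_m, m$fis_m)^2
  mult_r <- vf + vm
  pbar <- (m$p_f + m$p_m) / 2
  m$scaled_reproductive <- 4 * pbar * (1 - pbar) * m$fst_reproductive / mult_r

  rf <- m$sigma2_f / m$mu_f^2
  rm_ <- m$sigma2_m / m$mu_m^2
  mult_g <- (1 + rf) / (8 * m$n_f) + (1 + rm_) / (8 * m$n_m)
  mult_g[!is.finite(mult_g) | mult_g <= 0] <- NA_real_
  m$scaled_gametic <- m$fst_gametic / mult_g
  m
}

#' Compute the full per-site metric table for a cohort
#'
#' One-stop computation of adult/gametic/reproductive frequencies, per-sex LRS
#' moments and F_IS, the four between-sex F_ST metrics and their scaled
#' versions.
#'
#' @param x a [cohort()].
#' @param verbose log counts of sites with undefined metrics.
#' @return data.frame with one row per site: site metadata, `p_f`, `p_m`,
#'   `p_f_prime`, `p_m_prime`, `n_f`, `n_m`, `mu_*`, `sigma2_*`, `fis_*`,
#'   `maf`, `fst_adult`, `fst_reproductive`, `fst_gametic`, `fst_unfolded`,
#'   `scaled_adult`, `scaled_reproductive`, `scaled_gametic`.
#' @export
lifecycle_metrics <- function(x, verbose = FALSE) {
  counts <- site_counts(x)
  fr <- adult_frequencies(counts)
  pr <- project_gametic_frequencies(counts)
  mo <- lrs_moments(counts)
  fis_f <- estimate_fis(counts$f_n1 / counts$f_n, fr$p_f)
  fis_m <- estimate_fis(counts$m_n1 / counts$m_n, fr$p_m)
  pbar <- (fr$p_f + fr$p_m) / 2
  maf <- pmin(pbar, 1 - pbar)

  m <- data.frame(x$sites[, intersect(c("chrom", "pos", "ref", "alt"),
                                      names(x$sites)), drop = FALSE],
                  fr, pr, mo,
                  fis_f = fis_f, fis_m = fis_m, maf = maf)
  m$fst_adult <- fst_adult(m$p_f, m$p_m)
  m$fst_reproductive <- fst_reproductive(m$p_f, m$p_m, m$p_f_prime, m$p_m_prime)
  m$fst_gametic <- fst_gametic(m$p_f_prime, m$p_m_prime)
  m$fst_unfolded <- fst_unfolded(m$p_f, m$p_m, m$p_f_prime, m$p_m_prime,
                                 m$n_f, m$n_m, m$mu_f, m$mu_m,
                                 m$sigma2_f, m$sigma2_m, m$fis_f, m$fis_m)
  m <- scale_to_null(m)
  if (verbose) {
    for (col in c("scaled_adult", "scaled_reproductive", "scaled_gametic",
                  "fst_unfolded"))
      message(col, ": ", sum(is.na(m[[col]])), "/", nrow(m), " undefined")
  }
  m
}
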