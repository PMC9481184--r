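# The four between-sex F_ST metrics, their inputs and their null scaling.

test_that("adult frequencies come out of genotype counts correctly", {
  # females 30/40/30 (ALT-hom/het/REF-hom) -> 0.5; males 40/40/20 -> 0.6
  counts <- data.frame(f_n2 = 30, f_n1 = 40, f_n0 = 30, f_n = 100,
                       m_n2 = 40, m_n1 = 40, m_n0 = 20, m_n = 100)
  fr <- adult_frequencies(counts)
  expect_equal(fr$p_f, 0.5)
  expect_equal(fr$p_m, 0.6)
  # symmetry and fixation
  counts2 <- data.frame(f_n2 = 10, f_n1 = 17, f_n0 = 10, f_n = 37,
                        m_n2 = 0, m_n1 = 0, m_n0 = 25, m_n = 25)
  fr2 <- adult_frequencies(counts2)
  expect_equal(fr2$p_f, 0.5)
  expect_equal(fr2$p_m, 0)
  # a sex with no genotyped adults -> NA
  counts3 <- data.frame(f_n2 = 0, f_n1 = 0, f_n0 = 0, f_n = 0,
                        m_n2 = 1, m_n1 = 0, m_n0 = 0, m_n = 1)
  expect_true(is.na(adult_frequencies(counts3)$p_f))
})

test_that("gametic projection follows the LRS-weighted allele share", {
  counts <- data.frame(f_S2 = 10, f_S1 = 20, f_S0 = 10,
                       m_S2 = 10, m_S1 = 20, m_S0 = 10)
  pr <- project_gametic_frequencies(counts)
  expect_equal(pr$p_m_prime, 0.5)
  # all LRS carried by ALT homozygotes -> 1
  counts2 <- data.frame(f_S2 = 7, f_S1 = 0, f_S0 = 0,
                        m_S2 = 0, m_S1 = 0, m_S0 = 0)
  pr2 <- project_gametic_frequencies(counts2)
  expect_equal(pr2$p_f_prime, 1)
  expect_true(is.na(pr2$p_m_prime))  # zero total LRS in males
})

test_that("projection equals the individual-level weighted computation", {
  # oracle: sum_i lrs_i * g_i / 2 / sum_i lrs_i per sex
  for (seed in 1:5) {
    x <- make_random_cohort(n_sites = 12, n_f = 25, n_m = 25, seed = seed)
    counts <- site_counts(x)
    pr <- project_gametic_frequencies(counts)
    for (sx in c("F", "M")) {
      cols <- which(x$samples$sex == sx)
      w <- x$samples$lrs[cols]
      oracle <- apply(x$genotypes[, cols, drop = FALSE], 1, function(g) {
        ok <- !is.na(g)
        if (sum(w[ok]) == 0) return(NA_real_)
        sum(w[ok] * g[ok] / 2) / sum(w[ok])
      })
      got <- if (sx == "F") pr$p_f_prime else pr$p_m_prime
      expect_equal(got, oracle, tolerance = 1e-12)
    }
  }
})

test_that("per-capita LRS independent of genotype preserves frequency", {
  x <- make_random_cohort(n_sites = 10, n_f = 40, n_m = 40, seed = 3)
  x$samples$lrs <- rep(2L, 80)  # identical LRS for everyone
  counts <- site_counts(x)
  fr <- adult_frequencies(counts)
  pr <- project_gametic_frequencies(counts)
  expect_equal(pr$p_f_prime, fr$p_f, tolerance = 1e-12)
  expect_equal(pr$p_m_prime, fr$p_m, tolerance = 1e-12)
  # and reproductive F_ST is exactly zero
  expect_equal(fst_reproductive(fr$p_f, fr$p_m, pr$p_f_prime, pr$p_m_prime),
               rep(0, 10), tolerance = 1e-12)
})

test_that("F_ST kernels match hand-evaluated values", {
  expect_equal(fst_adult(0.6, 0.4), 0.04)
  expect_equal(fst_adult(0.5, 0.5), 0)
  expect_equal(fst_reproductive(0.5, 0.5, 0.55, 0.45), 0.01)
  expect_equal(fst_reproductive(0.4, 0.6, 0.45, 0.65), 0, tolerance = 1e-12)
  expect_equal(fst_gametic(0.55, 0.45), 0.01)
  # gametic is the adult kernel on primed frequencies
  expect_equal(fst_gametic(0.3, 0.7), fst_adult(0.3, 0.7))
  # monomorphic -> NA
  expect_true(is.na(fst_adult(0, 0)))
})

test_that("squared metrics are invariant to allele-label flips", {
  set.seed(9)
  pf <- runif(50, 0.05, 0.95); pm <- runif(50, 0.05, 0.95)
  pfp <- pmin(pmax(pf + rnorm(50, 0, 0.02), 0.01), 0.99)
  pmp <- pmin(pmax(pm + rnorm(50, 0, 0.02), 0.01), 0.99)
  expect_equal(fst_adult(pf, pm), fst_adult(1 - pf, 1 - pm))
  expect_equal(fst_reproductive(pf, pm, pfp, pmp),
               fst_reproductive(1 - pf, 1 - pm, 1 - pfp, 1 - pmp))
  expect_equal(fst_gametic(pfp, pmp), fst_gametic(1 - pfp, 1 - pmp))
  # unfolded too: both z factors flip sign
  u1 <- fst_unfolded(pf, pm, pfp, pmp, 100, 100, 1.8, 1.8, 1.8, 1.8, 0, 0)
  u2 <- fst_unfolded(1 - pf, 1 - pm, 1 - pfp, 1 - pmp, 100, 100,
                     1.8, 1.8, 1.8, 1.8, 0, 0)
  expect_equal(u1, u2)
})

test_that("unfolded metric matches its hand-evaluated example", {
  # each z = +-0.05 / sqrt(0.25/200) -> product -2 for opposing changes
  u <- fst_unfolded(p_f = 0.5, p_m = 0.5, p_f_prime = 0.55, p_m_prime = 0.45,
                    n_f = 100, n_m = 100, mu_f = 1, mu_m = 1,
                    sigma2_f = 1, sigma2_m = 1, fis_f = 0, fis_m = 0)
  expect_equal(u, -2, tolerance = 1e-12)
  u2 <- fst_unfolded(0.5, 0.5, 0.55, 0.55, 100, 100, 1, 1, 1, 1, 0, 0)
  expect_equal(u2, 2, tolerance = 1e-12)
  # zero change in either sex -> 0; sigma2 = 0 -> NA
  expect_equal(fst_unfolded(0.5, 0.5, 0.5, 0.45, 100, 100, 1, 1, 1, 1, 0, 0), 0)
  expect_true(is.na(fst_unfolded(0.5, 0.5, 0.55, 0.45, 100, 100, 1, 1, 0, 1, 0, 0)))
})

test_that("null scaling reproduces the hand-evaluated multipliers", {
  m <- data.frame(p_f = 0.5, p_m = 0.5, p_f_prime = 0.55, p_m_prime = 0.45,
                  n_f = 100, n_m = 100, mu_f = 1, mu_m = 1,
                  sigma2_f = 1, sigma2_m = 1, fis_f = 0, fis_m = 0)
  m$fst_adult <- fst_adult(0.6, 0.4)            # 0.04
  m$fst_reproductive <- fst_reproductive(0.5, 0.5, 0.55, 0.45)  # 0.01
  m$fst_gametic <- 0.01
  m$fst_unfolded <- -2
  out <- scale_to_null(m)
  expect_equal(out$scaled_adult, 0.04 / 0.0025)          # 16
  expect_equal(out$scaled_reproductive, 4.0)             # 0.01 / 0.0025
  expect_equal(out$scaled_gametic, 0.01 / (2 * (1 + 1) / 800))
  expect_equal(out$fst_unfolded, -2)                     # unchanged
})

test_that("LRS moments use the unbiased variance and flag degenerate sexes", {
  x <- make_toy_cohort(matrix(c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 1L), 2, 4),
                       sex = c("F", "F", "F", "F"), lrs = c(0L, 1L, 2L, 3L))
  counts <- site_counts(x)
  mo <- lrs_moments(counts)
  expect_equal(mo$mu_f[1], 1.5)
  expect_equal(mo$sigma2_f[1], 5 / 3)
  expect_true(all(is.na(mo$mu_m)))  # no males at all
})

test_that("F_IS follows the heterozygote-excess-positive convention", {
  expect_equal(estimate_fis(0.6, 0.5), 0.2)
  expect_equal(estimate_fis(0.4, 0.5), -0.2)
  expect_equal(estimate_fis(2 * 0.3 * 0.7, 0.3), 0)
  expect_true(is.na(estimate_fis(0, 0)))
})

test_that("missingness feeds into per-site sample sizes and moments", {
  g <- matrix(c(0L, NA, 2L, 1L,
                1L, 1L, NA, NA), 2, 4, byrow = TRUE)
  x <- make_toy_cohort(g, sex = c("F", "F", "M", "M"), lrs = c(5L, 1L, 2L, 4L))
  counts <- site_counts(x)
  expect_equal(counts$f_n, c(1, 2))
  expect_equal(counts$f_miss, c(1, 0))
  expect_equal(counts$m_n, c(2, 0))
  # site-1 female mean LRS over genotyped individuals only
  expect_equal(counts$f_mu[1], 5)
  expect_equal(counts$f_S0[1], 5)
})
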