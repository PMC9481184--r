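# Artefact-aware site QC: F_IS bounds, the three artefact tests, FDR, and the
# combined filter.

test_that("expected F_IS under SA selection matches hand evaluations", {
  p <- sa_filter_params()  # s_max = 0.2
  e1 <- expected_fis_under_sa(10000, 0.5, p)
  expect_equal(e1$mean, 1 / 20000 + 0.0625 * (0.2 / 0.9)^2, tolerance = 1e-9)
  expect_equal(e1$mean, 0.0031364, tolerance = 1e-4)
  expect_equal(e1$variance, 1e-4)
  e2 <- expected_fis_under_sa(100, 0.1, p)
  expect_equal(e2$mean, 1 / 200 + 0.0225 * (0.2 / 0.98)^2, tolerance = 1e-9)
  expect_equal(e2$mean, 0.0059372, tolerance = 1e-4)
  # neutral limit: s_max -> 0 leaves only the finite-sample term
  e3 <- expected_fis_under_sa(50, 0.3, sa_filter_params(s_max = 1e-9))
  expect_equal(e3$mean, 1 / 100, tolerance = 1e-6)
})

test_that("expected F_IS is monotone in s_max and in p(1-p)", {
  smax_grid <- c(0.05, 0.1, 0.2, 0.4)
  means <- vapply(smax_grid, function(s)
    expected_fis_under_sa(1000, 0.3, sa_filter_params(s_max = s))$mean,
    numeric(1))
  expect_true(all(diff(means) > 0))
  p_grid <- c(0.05, 0.1, 0.2, 0.3, 0.5)  # increasing p(1-p)
  means_p <- vapply(p_grid, function(p)
    expected_fis_under_sa(1000, p)$mean, numeric(1))
  expect_true(all(diff(means_p) > 0))
})

test_that("het-excess Z-test is one-tailed with the right centring", {
  par <- sa_filter_params()
  n <- 400; p <- 0.3
  e <- expected_fis_under_sa(n, p, par)
  expect_equal(het_excess_test(e$mean, n, p, par), 0.5)
  expect_equal(het_excess_test(e$mean + 1.96 * sqrt(1 / n), n, p, par),
               0.025, tolerance = 1e-3)
  expect_gt(het_excess_test(e$mean - 5 * sqrt(1 / n), n, p, par), 0.999)
  expect_true(is.na(het_excess_test(NA, n, p, par)))
})

test_that("hom-deficit binomial test matches closed forms", {
  expect_equal(hom_deficit_test(0, 100, 0.5), 0.75^100)
  expect_equal(hom_deficit_test(100, 100, 0.5), 1)
  # central case: k at the expectation, large n -> p near 0.5
  expect_equal(hom_deficit_test(2500, 10000, 0.5), 0.5, tolerance = 0.02)
})

test_that("sex-differential missingness chi-square matches brute force", {
  # 2x2 table (10, 990 | 40, 960): frozen from a chisq.test oracle
  p <- missing_diff_test(10, 990, 40, 960)
  oracle <- suppressWarnings(
    stats::chisq.test(matrix(c(10, 990, 40, 960), 2, byrow = TRUE),
                      correct = FALSE))
  expect_equal(p, oracle$p.value, tolerance = 1e-12)
  expect_equal(unname(oracle$statistic), 18.3, tolerance = 0.01)
  expect_lt(p, 2e-5)
  # homogeneous table -> p = 1; no missingness anywhere -> p = 1
  expect_equal(missing_diff_test(10, 90, 10, 90), 1)
  expect_equal(missing_diff_test(0, 100, 0, 100), 1)
  # zero margin -> NA
  expect_true(is.na(missing_diff_test(0, 0, 5, 95)))
})

test_that("BH q-values follow the step-up rule and pass NAs through", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.123), 0.123)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  q <- bh_fdr(c(0.01, NA, 0.5))
  expect_true(is.na(q[2]))
  # permutation equivariance: q-values travel with their p-values
  set.seed(1)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
})

test_that("exact HWE test agrees with a chi-square oracle away from tails", {
  # large balanced sample at HWE: exact p should be large
  expect_gt(hwe_exact_test(50, 25, 25), 0.5)
  # strong het deficit: both tests highly significant
  p_exact <- hwe_exact_test(10, 45, 45)
  counts <- c(AA = 45, Aa = 10, aa = 45)
  n <- sum(counts); p <- (2 * counts[1] + counts[2]) / (2 * n)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi <- sum((counts - expected)^2 / expected)
  p_chi <- pchisq(chi, 1, lower.tail = FALSE)
  expect_lt(p_exact, 1e-10)
  expect_lt(p_chi, 1e-10)
  # monomorphic -> 1
  expect_equal(hwe_exact_test(0, 0, 80), 1)
})

test_that("neutral panels are rarely flagged; injected artefacts are caught", {
  x <- simulate_cohort(sim_config(n_f = 2000, n_m = 2000, n_sites = 300,
                                  preset = "neutral", seed = 31))
  res <- suppressMessages(apply_site_filters(x, verbose = FALSE))
  qc <- res$qc
  # false-flag rate of each artefact family stays near/below the FDR level
  expect_lte(mean(qc$het_excess_q_combined < 0.05, na.rm = TRUE), 0.05)
  expect_lte(mean(qc$hom_deficit_q_combined < 0.05, na.rm = TRUE), 0.05)
  expect_lte(mean(qc$missing_diff_q < 0.05, na.rm = TRUE), 0.05)
  expect_gt(mean(qc$pass), 0.9)

  # inject heterozygote inflation at 20% of sites: those get flagged
  cfg <- sim_config(n_f = 2000, n_m = 2000, n_sites = 300, preset = "neutral",
                    seed = 32,
                    artefacts = list(het_inflation_frac = 0.2,
                                     het_inflation_strength = 1))
  x2 <- simulate_cohort(cfg)
  hit <- attr(x2, "artefact_sites")
  res2 <- suppressMessages(apply_site_filters(x2, verbose = FALSE))
  flagged <- grepl("het_excess|hom_deficit", res2$qc$reasons)
  expect_gt(mean(flagged[hit]), 0.9)          # sensitivity
  expect_lte(mean(flagged[-hit]), 0.05)       # specificity

  # sex-biased missingness is caught by the chi-square family
  cfg3 <- sim_config(n_f = 2000, n_m = 2000, n_sites = 100, preset = "neutral",
                     seed = 33,
                     artefacts = list(missing_rate = 0.01, missing_rate_m = 0.05))
  x3 <- simulate_cohort(cfg3)
  res3 <- suppressMessages(apply_site_filters(x3, verbose = FALSE))
  expect_gt(mean(res3$qc$missing_diff_q < 0.05, na.rm = TRUE), 0.9)
})

test_that("info-score handling follows the require-info flag", {
  x <- make_random_cohort(n_sites = 10, n_f = 50, n_m = 50, seed = 8)
  x$sites$info_score[3] <- NA
  x$sites$info_score[4] <- 0.5
  res <- suppressMessages(apply_site_filters(x, verbose = FALSE))
  expect_false(grepl("info", res$qc$reasons[3]))   # NA info retained by default
  expect_true(grepl("info", res$qc$reasons[4]))    # low info dropped
  res2 <- suppressMessages(apply_site_filters(x, require_info = TRUE,
                                              verbose = FALSE))
  expect_true(grepl("info", res2$qc$reasons[3]))
})
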