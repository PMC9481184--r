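# Theoretical and permutation nulls, LD pruning and the comparison battery.

test_that("theoretical null draws have the right moments", {
  th <- draw_theoretical_null("adult", 50000, seed = 1)
  expect_equal(mean(th$draws), 1, tolerance = 3 * sqrt(2 / 50000))
  un <- draw_theoretical_null("unfolded", 50000, seed = 2)
  expect_equal(mean(un$draws), 0, tolerance = 3 / sqrt(50000))
  tails <- tail_means_unfolded(un$draws)
  expect_equal(unname(tails["mean_positive"]), 2 / pi, tolerance = 0.02)
  expect_equal(unname(tails["mean_negative"]), -2 / pi, tolerance = 0.02)
  # reproducibility under the same seed
  expect_identical(draw_theoretical_null("gametic", 10, seed = 3)$draws,
                   draw_theoretical_null("gametic", 10, seed = 3)$draws)
})

test_that("sex-label permutation preserves counts and pooled frequencies", {
  x <- make_random_cohort(n_sites = 15, n_f = 40, n_m = 30, seed = 11)
  xp <- permute_sex_labels(x, seed = 99)
  expect_equal(table(xp$samples$sex), table(x$samples$sex))
  expect_identical(xp$genotypes, x$genotypes)
  pooled <- function(z) rowMeans(z$genotypes, na.rm = TRUE)
  expect_identical(pooled(xp), pooled(x))
  # stratified variant preserves per-stratum sex counts
  strata <- rep(1:2, length.out = 70)
  xs <- permute_sex_labels(x, seed = 100, strata = strata)
  for (b in 1:2)
    expect_equal(table(xs$samples$sex[strata == b]),
                 table(x$samples$sex[strata == b]))
})

test_that("LRS permutation leaves adult F_ST bit-identical", {
  x <- make_random_cohort(n_sites = 15, n_f = 40, n_m = 40, seed = 12)
  xp <- permute_lrs_within_sex(x, seed = 5)
  for (sx in c("F", "M"))
    expect_equal(sort(xp$samples$lrs[xp$samples$sex == sx]),
                 sort(x$samples$lrs[x$samples$sex == sx]))
  m0 <- lifecycle_metrics(x)
  m1 <- lifecycle_metrics(xp)
  expect_identical(m0$fst_adult, m1$fst_adult)
  expect_identical(m0$p_f, m1$p_f)
})

test_that("LD pruning removes duplicates, keeps independents, honours MAF", {
  set.seed(21)
  n <- 400
  a <- rbinom(n, 2, 0.5)
  # duplicated site: exactly one of the pair survives
  x1 <- make_toy_cohort(rbind(a, a), sex = rep(c("F", "M"), n / 2),
                        lrs = rpois(n, 2))
  expect_length(ld_prune(x1), 1L)
  # mutually uncorrelated sites: all survive
  g <- matrix(rbinom(5 * n, 2, 0.4), 5, n)
  x2 <- make_toy_cohort(g, sex = rep(c("F", "M"), n / 2), lrs = rpois(n, 2))
  expect_length(ld_prune(x2), 5L)
})

test_that("LD pruning chain follows the lower-MAF-removal rule", {
  set.seed(22)
  n <- 2000
  a <- rbinom(n, 2, 0.5)
  b <- a; flip <- sample(n, 80); b[flip] <- 0L   # r2 high with a, lower MAF
  c_ <- rbinom(n, 2, 0.3)                        # ~independent
  G <- rbind(a, b, c_)
  r2 <- cor(t(G))^2
  expect_gt(r2[1, 2], 0.2)
  expect_lt(r2[1, 3], 0.2)
  expect_lt(r2[2, 3], 0.2)
  maf <- pmin(rowMeans(G) / 2, 1 - rowMeans(G) / 2)
  expect_lt(maf[2], maf[1])
  x <- make_toy_cohort(G, sex = rep(c("F", "M"), n / 2), lrs = rpois(n, 2))
  kept <- ld_prune(x)
  # the lower-MAF member (site 2) of the correlated pair is removed
  expect_equal(kept, c(1L, 3L))
  expect_lt(cor(G[1, ], G[3, ])^2, 0.2)
  # an exact MAF tie removes the later genomic position
  Gt <- rbind(a, a, c_)
  xt <- make_toy_cohort(Gt, sex = rep(c("F", "M"), n / 2), lrs = rpois(n, 2))
  expect_equal(ld_prune(xt), c(1L, 3L))
})

test_that("comparison battery is quiet on self-comparison and finds shifts", {
  set.seed(30)
  null_draws <- rchisq(5000, 1)
  obs_same <- rchisq(5000, 1)
  rep0 <- compare_to_null(obs_same, null_draws, n_boot = 200, seed = 1)
  expect_gt(rep0$wilcoxon_p, 0.01)
  expect_gt(rep0$ks_p, 0.01)
  expect_true(abs(rep0$top1_excess_pct) < 60)  # binomial noise on 50 sites
  expect_true(rep0$ci95[1] <= 0 && rep0$ci95[2] >= 0)
  # clearly inflated observed data
  obs_big <- rchisq(5000, 1) * 1.5
  rep1 <- compare_to_null(obs_big, null_draws, n_boot = 200, seed = 2)
  expect_lt(rep1$wilcoxon_p, 1e-6)
  expect_gt(rep1$top1_excess_pct, 50)
  expect_gt(rep1$bootstrap_diff, 0)
  expect_lt(rep1$empirical_p, 0.05)
})

test_that("top-percentile chi-square matches the hand-computed example", {
  # 114 observed sites out of 10,000 above the null's 99th percentile:
  # excess 14%, chi-square (114-100)^2/100 + (9886-9900)^2/9900 ~ 1.98
  null_draws <- seq_len(10000) / 1000
  cut <- stats::quantile(null_draws, 0.99, names = FALSE)
  observed <- c(rep(cut - 1, 10000 - 114), rep(cut + 1, 114))
  rep_ <- compare_to_null(observed, null_draws, n_boot = 10, seed = 1)
  expect_equal(rep_$top_tail_count, 114)
  expect_equal(rep_$top1_excess_pct, 14)
  expect_equal(rep_$top1_chisq, (114 - 100)^2 / 100 + 14^2 / 9900,
               tolerance = 1e-9)
  expect_equal(rep_$top1_chisq, 1.98, tolerance = 0.01)
})

test_that("tail means and Bonferroni threshold are exact where closed-form", {
  expect_equal(tail_means_unfolded(c(-1, -3, 2)),
               c(mean_negative = -2, mean_positive = 2))
  flipped <- tail_means_unfolded(-c(-1, -3, 2))
  expect_equal(unname(flipped), c(-2, 2))
  expect_true(is.na(tail_means_unfolded(c(1, 2))["mean_negative"]))
  expect_equal(bonferroni_threshold(0.05, 1051949), 4.753e-8, tolerance = 1e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 1000), 5e-5)
})

test_that("per-site p-values are correct for both metric families", {
  out <- per_site_pvalues(c(3.841, 0, NA))
  expect_equal(out$p[1], 0.05, tolerance = 1e-3)
  expect_equal(out$p[2], 1)
  expect_true(is.na(out$p[3]))
  # unfolded two-tailed p-values against a Monte-Carlo oracle
  set.seed(41)
  draws <- rnorm(2e6) * rnorm(2e6)
  for (q in c(0.5, 1, 2)) {
    mc <- mean(abs(draws) >= q)
    expect_equal(per_site_pvalues(q, metric = "unfolded")$p, mc,
                 tolerance = 0.02)
  }
  expect_equal(per_site_pvalues(0, metric = "unfolded")$p, 1)
})

test_that("neutral-simulation scaled metrics are calibrated after permutation", {
  x <- simulate_cohort(sim_config(n_f = 3000, n_m = 3000, n_sites = 800,
                                  preset = "neutral", seed = 55))
  mp <- lifecycle_metrics(permute_sex_labels(x, seed = 56))
  ks <- suppressWarnings(stats::ks.test(mp$scaled_adult, stats::pchisq, df = 1))
  expect_gt(ks$p.value, 0.01)
  # LRS permutation calibrates the reproductive metric even under
  # sex-differential viability
  xv <- simulate_cohort(sim_config(n_f = 3000, n_m = 3000, n_sites = 800,
                                   preset = "viability_sa", seed = 57))
  mv <- lifecycle_metrics(permute_lrs_within_sex(xv, seed = 58))
  ks2 <- suppressWarnings(stats::ks.test(mv$scaled_reproductive,
                                         stats::pchisq, df = 1))
  expect_gt(ks2$p.value, 0.01)
  expect_equal(mean(mv$scaled_reproductive, na.rm = TRUE), 1, tolerance = 0.15)
})
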