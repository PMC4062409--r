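test_that("pooled t-test matches the closed-form example and handles degenerate genes", {
  m <- make_em(rbind(c(0, 1, 2, 1, 2, 3), c(1, 1, 2, 1, 1, 2)), n_a = 3)
  tr <- row_t_test(m)
  # groups [0,1,2] vs [1,2,3]: pooled s^2 = 1, t = -1/sqrt(2/3)
  expect_equal(tr$statistic[1], -sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(tr$p_raw[1], 2 * pt(-sqrt(3 / 2), 4), tolerance = 1e-12)
  expect_equal(round(tr$statistic[1], 4), -1.2247)
  expect_equal(tr$p_raw[1], 0.2879, tolerance = 2e-4)
  # identical groups -> t = 0, p = 1
  expect_equal(tr$statistic[2], 0)
  expect_equal(tr$p_raw[2], 1)

  flat <- make_em(rbind(c(1, 1, 2, 2), c(3, 3, 3, 3)))
  expect_message(tf <- row_t_test(flat), "zero pooled variance")
  expect_equal(tf$p_raw, c(0, 1))
})

test_that("all tests are invariant under a common shift", {
  m <- random_em(15, 4, 4, seed = 12)
  shifted <- m
  shifted$values <- m$values + 7.5
  expect_equal(row_t_test(shifted)$p_raw, row_t_test(m)$p_raw)
  expect_equal(row_moderated_t(shifted)$p_raw, row_moderated_t(m)$p_raw)
  expect_equal(row_wilcoxon(shifted)$p_raw, row_wilcoxon(m)$p_raw)
  expect_equal(row_n_test(shifted, 50, seed = 2)$p_raw,
               row_n_test(m, 50, seed = 2)$p_raw)
})

test_that("t-test p-values are uniform under the null", {
  cfg <- random_effect_config(G = 10000, n = 5, n_up = 0, n_down = 0,
                              sigma2 = 1, rho = 0, seed = 77)
  sim <- simulate_random_effect(cfg)
  p <- row_t_test(sim$matrix)$p_raw
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(10000))  # 1% critical value
})

test_that("moderated t collapses to ordinary t in the no-heterogeneity limits", {
  # forced prior_df = 0: no shrinkage
  m <- random_em(25, 5, 5, seed = 13)
  t_plain <- row_t_test(m)
  t_mod0 <- row_moderated_t(m, prior_df = 0)
  expect_equal(t_mod0$statistic, t_plain$statistic, tolerance = 1e-12)

  # identical gene variances: shrunken variance equals the common value
  withr::with_seed(14, {
    base <- rnorm(8)
    v <- t(vapply(1:12, function(i) base + i * 10, numeric(8)))
  })
  em <- make_em(v)   # every gene is base + constant: equal variances
  tm <- row_moderated_t(em)
  s2 <- sum((base[1:4] - mean(base[1:4]))^2 + (base[5:8] - mean(base[5:8]))^2) / 6
  diff <- mean(base[1:4]) - mean(base[5:8])
  expect_equal(tm$statistic, rep(diff / sqrt(s2 / 2), 12), tolerance = 1e-10)
  expect_equal(attr(tm, "prior_df"), Inf)

  expect_error(row_moderated_t(make_em(v[1, , drop = FALSE])))
})

test_that("moderated t agrees with the limma empirical-Bayes fit", {
  library(limma)
  m <- random_em(200, 5, 5, seed = 15, sd = 2)
  # heterogeneous variances so shrinkage is non-trivial
  m$values <- m$values * sqrt(rchisq(200, 5) / 5)
  tm <- row_moderated_t(m)

  design <- cbind(1, as.numeric(m$groups == "A"))
  fit <- eBayes(lmFit(m$values, design))
  expect_equal(attr(tm, "prior_df"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(tm, "prior_var"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(tm$statistic, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(tm$p_raw, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("Wilcoxon exact and approximate p-values behave as documented", {
  m <- make_em(rbind(c(1, 2, 3, 4, 5, 6), c(2, 4, 6, 1, 3, 5)), n_a = 3)
  w <- row_wilcoxon(m)
  expect_equal(w$p_raw[1], 0.1)   # 2 / choose(6,3) extreme allocations

  # swapping labels leaves p unchanged
  sw <- m
  sw$groups[] <- c("B", "B", "B", "A", "A", "A")
  expect_equal(row_wilcoxon(sw)$p_raw, w$p_raw)

  # normal approximation close to exact enumeration at n = 6 + 6: the
  # continuity-corrected approximation sits within 0.02 everywhere (the
  # worst deviations are mid-range), and much closer on average
  big <- random_em(40, 6, 6, seed = 16)
  pe <- row_wilcoxon(big, exact = TRUE)$p_raw
  pa <- row_wilcoxon(big, exact = FALSE)$p_raw
  expect_lt(max(abs(pe - pa)), 0.02)
})

test_that("N-statistic: printed toy value, multiset zero, shift invariance", {
  expect_equal(n_statistic(c(0, 1), c(2, 3)), 3)
  expect_equal(n_statistic(c(1, 2, 2), c(2, 1, 2)), 0)
  x <- rnorm(5); y <- rnorm(7)
  expect_equal(n_statistic(x + 3, y + 3), n_statistic(x, y), tolerance = 1e-12)
  expect_gte(n_statistic(x, y), 0)
  expect_error(n_statistic(numeric(0), y), "non-empty")
})

test_that("N-test permutation p-values: bounds, null behaviour, enumeration oracle", {
  m <- random_em(5, 3, 3, seed = 18)
  nt <- row_n_test(m, n_perm = 99, seed = 1)
  expect_true(all(nt$p_raw >= 1 / 100 & nt$p_raw <= 1))
  expect_equal(row_n_test(m, n_perm = 99, seed = 1)$p_raw, nt$p_raw)

  # identical groups: observed N = 0 is never exceeded strictly -> p near 1
  same <- make_em(rbind(c(1, 2, 3, 1, 2, 3), c(4, 6, 5, 4, 6, 5)), n_a = 3)
  expect_true(all(row_n_test(same, 99, seed = 3)$p_raw > 0.5))

  # exhaustive-split oracle for one gene, n_A = n_B = 3
  x <- c(0.1, 1.3, 2.9); y <- c(0.8, 3.4, 4.1)
  obs <- n_statistic(x, y)
  all6 <- c(x, y)
  splits <- combn(6, 3)
  exceed <- apply(splits, 2, function(ia)
    n_statistic(all6[ia], all6[-ia]) >= obs - 1e-12)
  p_exact <- mean(exceed)
  mg <- make_em(rbind(all6, all6 * 0 + seq_along(all6)), n_a = 3)
  mg$values[1, ] <- all6
  p_mc <- row_n_test(mg, n_perm = 4000, seed = 9)$p_raw[1]
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(p_mc - p_exact), 3 * se + 2 / 4001)
})

test_that("every test holds its nominal size under an independent null", {
  cfg <- random_effect_config(G = 1200, n = 8, n_up = 0, n_down = 0,
                              sigma2 = 0.5, rho = 0, seed = 19)
  m <- simulate_random_effect(cfg)$matrix
  G <- 1200
  band <- 3 * sqrt(0.05 * 0.95 / G)
  expect_lt(abs(mean(row_t_test(m)$p_raw < 0.05) - 0.05), band)
  expect_lt(abs(mean(row_moderated_t(m)$p_raw < 0.05) - 0.05), band)
  expect_lt(abs(mean(row_wilcoxon(m)$p_raw < 0.05) - 0.05), band + 0.01)
  expect_lt(abs(mean(row_n_test(m, 199, seed = 20)$p_raw < 0.05) - 0.045),
            band + 0.005)
})

test_that("t-test power rises with effect size and with sample size", {
  mean_tp <- function(effect, n) {
    cfg <- random_effect_config(G = 200, n = n, n_up = 10, n_down = 10,
                                mu_up = effect, mu_down = -effect,
                                sigma2 = 0.1286, rho = 0.894, seed = 0)
    mean(vapply(derive_seeds(23, 20), function(s) {
      cfg$seed <- s
      sim <- simulate_random_effect(cfg)
      p <- row_t_test(sim$matrix)$p_raw
      sum(p[sim$truth$class_of != "null"] < 0.05)
    }, numeric(1)))
  }
  expect_gt(mean_tp(1.0, 5), mean_tp(0.4, 5))
  expect_gt(mean_tp(0.4, 16), mean_tp(0.4, 5))
})
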