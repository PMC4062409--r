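test_that("the random-effect generator is a pure function of its config", {
  cfg <- random_effect_config(G = 100, n = 5, n_up = 10, n_down = 5,
                              mu_up = 1, mu_down = -1, seed = 51)
  s1 <- simulate_random_effect(cfg)
  s2 <- simulate_random_effect(cfg)
  expect_identical(s1$matrix$values, s2$matrix$values)
  expect_identical(s1$truth$class_of, s2$truth$class_of)
  cfg$seed <- 52
  expect_false(identical(simulate_random_effect(cfg)$matrix$values,
                         s1$matrix$values))
})

test_that("config invariants are enforced", {
  expect_error(random_effect_config(G = 50, n_up = 40, n_down = 20), "exceed")
  expect_error(random_effect_config(sigma2 = 0), "positive")
  expect_error(random_effect_config(rho = 1), "rho")
  expect_error(random_effect_config(n = 1), "arrays")
})

test_that("simulated moments recover sigma2, rho and the effect sizes", {
  cfg <- random_effect_config(G = 1000, n = 10, n_up = 60, n_down = 40,
                              mu_up = 1.8, mu_down = -1.8,
                              sigma2 = 0.1286, rho = 0.894, seed = 0)
  seeds <- derive_seeds(53, 10)
  stats <- vapply(seeds, function(s) {
    cfg$seed <- s
    sim <- simulate_random_effect(cfg)
    cls <- sim$truth$class_of
    d <- group_mean_difference(sim$matrix)
    # mean pairwise correlation over a null-gene subset, group B arrays
    sub <- sim$matrix$values[which(cls == "null")[1:100],
                             group_cols(sim$matrix, "B")]
    cmat <- cor(t(sub))
    c(v = avg_within_group_variance(sim$matrix),
      r = mean(cmat[upper.tri(cmat)]),
      up = mean(d[cls == "up"]), down = mean(d[cls == "down"]))
  }, numeric(4))
  est <- rowMeans(stats)
  se <- apply(stats, 1, sd) / sqrt(ncol(stats))
  expect_lt(abs(est["v"] - 0.1286), 3 * se["v"])
  expect_lt(abs(est["r"] - 0.894), 3 * se["r"] + 0.02)
  expect_lt(abs(est["up"] - 1.8), 3 * se["up"])
  expect_lt(abs(est["down"] + 1.8), 3 * se["down"])
})

test_that("rho = 0 gives uncorrelated genes", {
  cfg <- random_effect_config(G = 200, n = 50, n_up = 0, n_down = 0,
                              sigma2 = 1, rho = 0, seed = 54)
  sim <- simulate_random_effect(cfg)
  cmat <- cor(t(sim$matrix$values[1:80, group_cols(sim$matrix, "A")]))
  expect_lt(abs(mean(cmat[upper.tri(cmat)])), 0.02)
})

test_that("presets encode the three scenarios and the two structures", {
  s3 <- simu_preset("SIMU3", "unbalanced", 10)
  expect_equal(s3$n, 10L)
  expect_equal(s3$mu_up, 1.8)
  expect_equal(s3$mu_down, -1.8)
  expect_equal(s3$n_up, 60L)
  expect_equal(s3$n_down, 40L)
  expect_equal(s3$G, 1000L)
  expect_equal(s3$sigma2, 0.1286)
  expect_equal(s3$rho, 0.894)
  expect_equal(s3$reps, 20L)

  s1 <- simu_preset("SIMU1", "balanced", 0.6)
  expect_equal(s1$n, 10L)           # fixed sample size; tuning is the effect
  expect_equal(s1$mu_up, 0.6)
  expect_equal(s1$n_up, 50L)
  expect_equal(s1$n_down, 50L)
  expect_equal(simu_preset("SIMU1", "unbalanced", 1.0)$n_up, 60L)

  s2 <- simu_preset("SIMU2", "balanced", 40)
  expect_equal(s2$mu_up, 1.0)       # fixed small effect; tuning is n
  expect_equal(s2$n, 40L)
  expect_error(simu_preset("SIMU4", "balanced", 1))
})

test_that("quantile normalization compresses SIMU3 effect sizes to about half", {
  cfg <- simu_preset("SIMU3", "unbalanced", 10, seed = 55)
  sim <- simulate_random_effect(cfg)
  d_raw <- group_mean_difference(sim$matrix)
  d_q <- group_mean_difference(normalize_quantile(sim$matrix))
  up <- sim$truth$class_of == "up"
  expect_equal(mean(d_raw[up]), 1.8, tolerance = 0.1)
  expect_gt(mean(d_q[up]), 0.85)
  expect_lt(mean(d_q[up]), 1.15)
})

test_that("synthetic seed matrix hits its construction targets", {
  sm <- synthetic_seed_matrix(G = 400, n_arrays = 80, seed = 56)
  expect_identical(synthetic_seed_matrix(G = 400, n_arrays = 80, seed = 56)$values,
                   sm$values)
  vars <- apply(sm$values, 1, var)
  expect_lt(abs(mean(vars) / 0.15 - 1), 0.1)
  cmat <- cor(t(sm$values[1:120, ]))
  mean_r <- mean(cmat[upper.tri(cmat)])
  expect_gt(mean_r, 0.85)
  expect_lt(mean_r, 0.95)
  expect_error(synthetic_seed_matrix(G = 1, n_arrays = 10), "G >= 2")
})

test_that("resampling produces exchangeable groups and recovers spiked effects", {
  sm <- synthetic_seed_matrix(G = 300, n_arrays = 60, seed = 57)
  spiked <- stats::setNames(c(rep(1.5, 15), rep(-1.5, 5)),
                            rownames(sm$values)[1:20])
  cfg <- resample_config(sm, n = 10, deg_effects = spiked, seed = 58)
  sim <- simulate_resample(cfg)
  expect_equal(ncol(sim$matrix$values), 20)
  expect_equal(unname(table(sim$matrix$groups)["A"]), 10L, ignore_attr = TRUE)
  expect_equal(sum(sim$truth$class_of == "up"), 15)
  expect_equal(sum(sim$truth$class_of == "down"), 5)
  expect_identical(simulate_resample(cfg)$matrix$values, sim$matrix$values)

  # spiked mean difference across resamples ~ the spiked effect
  diffs <- vapply(derive_seeds(59, 15), function(s) {
    cfg$seed <- s
    d <- group_mean_difference(simulate_resample(cfg)$matrix)
    mean(d[sim$truth$class_of == "up"])
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 1.5), 3 * se)

  expect_error(resample_config(sm, n = 40), "exceeds")
  expect_error(resample_config(sm, n = 5, deg_effects = c(nope = 1)),
               "gene ids")
})

test_that("a pure resampling null keeps the t-test near its nominal level", {
  sm <- synthetic_seed_matrix(G = 300, n_arrays = 60, seed = 60)
  rates <- vapply(derive_seeds(61, 20), function(s) {
    cfg <- resample_config(sm, n = 8, seed = s)
    mean(row_t_test(simulate_resample(cfg)$matrix)$p_raw < 0.05)
  }, numeric(1))
  expect_gt(mean(rates), 0.01)
  expect_lt(mean(rates), 0.10)
})
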