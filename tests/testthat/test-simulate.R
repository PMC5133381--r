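test_that("config validation rejects impossible settings", {
  expect_error(mr_sim_config(J = 1), "J must be")
  expect_error(mr_sim_config(gamma_range = c(-0.1, 0.2)), "positive")
  expect_error(mr_sim_config(se_outcome = -1), "non-negative")
  expect_error(mr_sim_config(invalid_fraction = 1.2), "invalid_fraction")
  expect_error(mr_sim_config(pleiotropy = "weird"), "arg")
  expect_error(mr_sim_config(pleiotropy_scale = -0.1), "pleiotropy_scale")
  expect_error(mr_sim_config(inside_correlation = 2), "inside_correlation")
  # no pleiotropy forces the invalid fraction to zero
  expect_equal(mr_sim_config(invalid_fraction = 0.5)$invalid_fraction, 0)
})

test_that("the same seed reproduces the dataset; different seeds do not", {
  cfg <- mr_sim_config(J = 12, theta = 0.1)
  s1 <- simulate_mr_dataset(cfg, seed = 4)
  s2 <- simulate_mr_dataset(cfg, seed = 4)
  s3 <- simulate_mr_dataset(cfg, seed = 5)
  expect_identical(s1$data$variants, s2$data$variants)
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(s1$data$variants, s3$data$variants))
})

test_that("the noise-free limit returns the causal effect exactly for every variant", {
  cfg <- mr_sim_config(J = 6, theta = 0.37, se_exposure = 0,
                       se_outcome = 0)
  sim <- simulate_mr_dataset(cfg, seed = 2)
  v <- sim$data$variants
  expect_equal(v$beta_outcome / v$beta_exposure, rep(0.37, 6))
  expect_equal(v$beta_exposure, sim$truth$gamma)
})

test_that("the generator's marginals match their stated distributions", {
  cfg <- mr_sim_config(J = 1e4, theta = 0, invalid_fraction = 0.5,
                       pleiotropy = "balanced", pleiotropy_scale = 0.04)
  sim <- simulate_mr_dataset(cfg, seed = 10)
  tr <- sim$truth
  expect_true(all(tr$gamma >= 0.05 & tr$gamma <= 0.15))
  expect_gt(ks.test((tr$gamma - 0.05) / 0.1, "punif")$p.value, 1e-3)
  n_inv <- sum(!tr$valid)
  expect_equal(n_inv, 5000L)
  expect_true(all(which(!tr$valid) == 1:5000))
  expect_true(all(tr$alpha[tr$valid] == 0))
  a <- tr$alpha[!tr$valid]
  expect_lt(abs(mean(a)), 3 * 0.04 / sqrt(n_inv))
  expect_lt(abs(cor(a, tr$gamma[!tr$valid])), 3 / sqrt(n_inv))
})

test_that("directional and InSIDE-violating architectures have the stated structure", {
  cfg_d <- mr_sim_config(J = 5000, theta = 0, invalid_fraction = 1,
                         pleiotropy = "directional",
                         pleiotropy_scale = 0.1)
  a_d <- simulate_mr_dataset(cfg_d, seed = 11)$truth$alpha
  expect_true(all(a_d >= 0 & a_d <= 0.1))
  expect_lt(abs(mean(a_d) - 0.05), 3 * (0.1 / sqrt(12)) / sqrt(5000))
  # the strength-linked component is small against its own noise, so test
  # the correlation's sign at 3 standard errors rather than a fixed size
  cfg_i <- mr_sim_config(J = 50000, theta = 0, invalid_fraction = 1,
                         pleiotropy = "inside_violated",
                         pleiotropy_scale = 0.1,
                         inside_correlation = 0.8)
  tr_i <- simulate_mr_dataset(cfg_i, seed = 12)$truth
  expect_gt(cor(tr_i$alpha, tr_i$gamma), 3 / sqrt(50000))
  # and the Egger slope is biased in the configured direction
  cfg_small <- mr_sim_config(J = 50, theta = 0, invalid_fraction = 1,
                             pleiotropy = "inside_violated",
                             pleiotropy_scale = 0.1,
                             inside_correlation = 0.8)
  slopes <- vapply(1:200, function(r)
    mr_egger(simulate_mr_dataset(cfg_small, seed = 600 + r)$data)$beta,
    numeric(1))
  expect_gt(mean(slopes), 3 * sd(slopes) / sqrt(200))
})

test_that("operating characteristics summarise replicates with a seed trail", {
  cfg <- mr_sim_config(J = 10, theta = 0.2)
  oc <- operating_characteristics(cfg, "ivw", n_sims = 50, seed = 7,
                                  model = "fixed")
  expect_equal(oc$n_sims, 50L)
  expect_equal(oc$n_failed, 0L)
  expect_gte(oc$rmse^2 + 1e-15, oc$bias^2)
  expect_equal(oc$mc_se, sqrt(oc$rejection_rate *
                                (1 - oc$rejection_rate) / 50))
  # replicate r is regenerable in isolation from seed + r
  redo <- mr_ivw(simulate_mr_dataset(cfg, seed = 7 + 3)$data, "fixed")
  expect_equal(oc$betas[3], redo$beta)
  oc2 <- operating_characteristics(cfg, "ivw", n_sims = 50, seed = 7,
                                   model = "fixed")
  expect_identical(oc$betas, oc2$betas)
})

test_that("weighted-median bias shrinks with precision while IVW bias persists", {
  # 30% invalid weight, directional pleiotropy: over a precision ladder the
  # median tracks the true null but IVW stays biased
  lad <- c(0.03, 0.015, 0.0075)
  med_bias <- ivw_bias <- numeric(length(lad))
  for (i in seq_along(lad)) {
    cfg <- mr_sim_config(J = 20, theta = 0, invalid_fraction = 0.3,
                         pleiotropy = "directional",
                         pleiotropy_scale = 0.1, se_outcome = lad[i],
                         se_exposure = lad[i] / 6)
    m <- v <- numeric(150)
    for (r in seq_len(150)) {
      sim <- simulate_mr_dataset(cfg, seed = 40000 + 1000 * i + r)
      m[r] <- mr_weighted_median(sim$data, n_boot = 2, seed = 1)$beta
      v[r] <- mr_ivw(sim$data)$beta
    }
    med_bias[i] <- mean(m)
    ivw_bias[i] <- mean(v)
  }
  expect_lt(med_bias[3], med_bias[1])          # median bias shrinks
  expect_lt(med_bias[3], 0.5 * ivw_bias[3])    # and undercuts IVW's
  expect_gt(ivw_bias[3], 0.5 * ivw_bias[1])    # which does not vanish
})
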