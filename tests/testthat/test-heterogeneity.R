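test_that("identical ratio estimates give Q = 0, p = 1, I^2 = 0", {
  d <- dataset_from_ratios(rep(0.3, 4), c(1, 2, 0.5, 1))
  het <- cochran_q(d)
  expect_equal(het$Q, 0)
  expect_equal(het$p_value, 1)
  expect_equal(het$i_squared, 0)
  expect_equal(het$contributions$q, rep(0, 4))
})

test_that("two equal-precision estimates one unit apart give Q = 0.5 on 1 df", {
  het <- cochran_q(dataset_from_ratios(c(1, 2), c(1, 1)))
  expect_equal(het$Q, 0.5)
  expect_equal(het$df, 1L)
  expect_equal(het$p_value, pchisq(0.5, 1, lower.tail = FALSE))
})

test_that("contributions are non-negative and sum to Q; J = 2 matches the closed form", {
  for (seed in 1:25) {
    d <- rand_dataset(sample(2:15, 1), seed = seed)
    het <- cochran_q(d)
    expect_true(all(het$contributions$q >= 0))
    expect_equal(sum(het$contributions$q), het$Q, tolerance = 1e-10)
    expect_equal(het$i_squared,
                 if (het$Q == 0) 0 else max(0, (het$Q - het$df) / het$Q))
    d2 <- rand_dataset(2, seed = seed + 100)
    r <- ratio_estimates(orient_exposure(d2))
    expect_equal(cochran_q(d2)$Q,
                 (r$theta[1] - r$theta[2])^2 / (r$se[1]^2 + r$se[2]^2),
                 tolerance = 1e-10)
  }
})

test_that("Q agrees with a generic inverse-variance meta-analysis", {
  skip_if_not_installed("metafor")
  d <- orient_exposure(rand_dataset(14, seed = 41))
  r <- ratio_estimates(d)
  ma <- metafor::rma(yi = r$theta, sei = r$se, method = "FE")
  expect_equal(cochran_q(d)$Q, as.numeric(ma$QE), tolerance = 1e-10)
})

test_that("Q is invariant under reordering and joint sign flips", {
  d <- rand_dataset(9, seed = 55)
  expect_equal(cochran_q(d[9:1])$Q, cochran_q(d)$Q)
})

test_that("the default pruning threshold is the upper 95th percentile of chi-squared(1)", {
  expect_equal(formals(prune_outliers)$threshold,
               quote(stats::qchisq(0.95, df = 1)))
  expect_equal(round(qchisq(0.95, df = 1), 2), 3.84)
})

test_that("pruning removes a constructed gross outlier and nothing else", {
  d <- dataset_from_ratios(rep(0.2, 10), rep(0.1, 10))
  homog <- prune_outliers(d)
  expect_length(homog$removed, 0)
  expect_equal(n_variants(homog$data), 10)
  # one variant displaced by 10 combined SDs
  out <- dataset_from_ratios(c(rep(0.2, 10), 0.2 + 10 * sqrt(2) * 0.1),
                             rep(0.1, 11))
  pr <- prune_outliers(out)
  expect_equal(pr$removed, "v11")
  expect_equal(n_variants(pr$data), 10)
  pr_it <- prune_outliers(out, iterative = TRUE)
  expect_equal(pr_it$removed, "v11")
})

test_that("pruning that would leave fewer than 2 variants errors with the trail", {
  d <- dataset_from_ratios(c(0, 10, 20), c(0.1, 0.1, 0.1))
  expect_error(prune_outliers(d), "fewer than 2")
})

test_that("the directional-pleiotropy test reports the Egger intercept block", {
  bx <- c(0.05, 0.1, 0.15, 0.2)
  exact <- mr_dataset(paste0("v", 1:4), bx, rep(0.01, 4), 0.5 * bx,
                      rep(0.02, 4))
  tst <- directional_pleiotropy_test(exact)
  expect_equal(tst$estimate, 0, tolerance = 1e-12)
  expect_gt(tst$p_value, 0.99)
  shifted <- mr_dataset(paste0("v", 1:4), bx, rep(0.01, 4),
                        0.1 + 0.5 * bx, rep(0.02, 4))
  expect_equal(directional_pleiotropy_test(shifted)$estimate, 0.1)
})

test_that("the Q test holds its nominal level under simulated homogeneity", {
  cfg <- mr_sim_config(J = 10, theta = 0)
  n_sims <- 500
  rej <- logical(n_sims)
  for (r in seq_len(n_sims))
    rej[r] <- cochran_q(simulate_mr_dataset(cfg, seed = 9000 + r)$data)$p_value < 0.05
  mc <- sqrt(0.05 * 0.95 / n_sims)
  expect_lt(abs(mean(rej) - 0.05), 3 * mc)
})
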