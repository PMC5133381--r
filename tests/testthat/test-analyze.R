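test_that("homogeneous input gives concordant methods and a quiet Q test", {
  bx <- c(0.08, 0.12, 0.16)
  d <- mr_dataset(paste0("v", 1:3), bx, rep(0.01, 3), 0.5 * bx,
                  rep(0.02, 3))
  rep <- mr_analyze(d, seed = 2, n_boot = 100, loo = TRUE)
  est <- rep$estimates
  expect_true(all(est$status == "ok"))
  expect_equal(est$beta[est$method == "ivw" & est$model == "fixed"], 0.5)
  spread <- max(est$beta) - min(est$beta)
  expect_lt(spread, 2 * max(est$se))
  expect_gt(rep$heterogeneity$p_value, 0.05)
})

test_that("insufficient variants route Egger and medians to 'not computed'", {
  d <- rand_dataset(2, seed = 111)
  rep <- mr_analyze(d, seed = 1, loo = FALSE)
  est <- rep$estimates
  expect_true(all(grepl("not computed", est$status[est$method %in%
    c("egger", "simple_median", "weighted_median")])))
  expect_equal(est$status[est$method == "ivw"], c("ok", "ok"))
  expect_s3_class(rep$heterogeneity, "mr_het")
  expect_match(rep$pleiotropy, "at least 3")
})

test_that("reports are byte-identical across runs with the same seed", {
  d <- rand_dataset(6, seed = 112)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_mr_report(mr_analyze(d, seed = 9, n_boot = 50), f1)
  write_mr_report(mr_analyze(d, seed = 9, n_boot = 50), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("an exposure SD turns log-odds estimates into per-SD odds ratios", {
  d <- rand_dataset(6, seed = 113)
  rep <- mr_analyze(d, exposure_sd = 1.05, seed = 1, n_boot = 50,
                    loo = FALSE)
  est <- rep$estimates
  expect_equal(est$or_per_sd, exp(est$beta * 1.05))
  expect_true(all(est$or_ci_low < est$or_per_sd &
                    est$or_per_sd < est$or_ci_high))
})

test_that("odds-ratio conversion is monotone, errors on linear outcomes, and nulls to 1", {
  d <- rand_dataset(5, seed = 114)
  fit <- mr_ivw(d)
  or <- to_odds_ratio(fit, exposure_sd = 1.05)
  expect_equal(or$or, exp(fit$beta * 1.05))
  expect_true(or$ci_low < or$or && or$or < or$ci_high)
  null_fit <- fit
  null_fit$beta <- 0
  expect_equal(to_odds_ratio(null_fit, 2)$or, 1)
  lin <- rand_dataset(5, seed = 115)
  lin$outcome_scale <- "linear"
  expect_error(to_odds_ratio(mr_ivw(lin), 1), "log-odds")
})

test_that("the bundled synthetic example dataset loads and analyses end to end", {
  path <- system.file("extdata", "crp_cad_synthetic.csv",
                      package = "mrsens")
  d <- read_mr_dataset(path, exposure_label = "log CRP (synthetic)",
                       outcome_label = "CAD log odds (synthetic)",
                       exposure_sd = 1.05)
  expect_equal(n_variants(d), 17L)
  rep <- mr_analyze(d, seed = 4, n_boot = 100)
  expect_true(all(rep$estimates$status == "ok"))
  expect_s3_class(rep$heterogeneity, "mr_het")
  expect_gt(rep$heterogeneity$Q, qchisq(0.95, df = 16))
})

test_that("the command-line wrapper analyses a file end to end", {
  skip_if_not_installed("optparse")
  cli <- system.file("cli", "mrsens.R", package = "mrsens")
  data <- system.file("extdata", "crp_cad_synthetic.csv",
                      package = "mrsens")
  out <- tempfile(fileext = ".json")
  res <- system2("Rscript", c(cli, "analyze", "--in", shQuote(data),
                              "--exposure-sd", "1.05", "--seed", "3",
                              "--out-json", shQuote(out)),
                 stdout = TRUE, stderr = TRUE)
  expect_equal(attr(res, "status"), NULL)
  expect_true(file.exists(out))
  js <- jsonlite::read_json(out)
  expect_equal(js$dataset$n_variants, 17L)
  expect_equal(length(js$estimates), 6L)
})
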