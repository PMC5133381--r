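test_that("delimited files parse with column maps, preserving row order", {
  path <- write_csv_fixture(c("snp,bx,bxse,by,byse",
                              "rs2,0.10,0.01,0.05,0.02",
                              "rs1,-0.20,0.02,0.08,0.03"))
  d <- read_mr_dataset(path, column_map = c(variant = "snp",
                                            beta_exposure = "bx",
                                            se_exposure = "bxse",
                                            beta_outcome = "by",
                                            se_outcome = "byse"))
  expect_s3_class(d, "mr_dataset")
  expect_equal(n_variants(d), 2L)
  expect_equal(d$variants$variant, c("rs2", "rs1"))
  expect_equal(d$variants$beta_exposure, c(0.10, -0.20))
  expect_false(d$oriented)
})

test_that("tab delimiter is auto-detected and scientific notation parses", {
  path <- write_csv_fixture(
    c("variant\tbeta_exposure\tse_exposure\tbeta_outcome\tse_outcome",
      "rs1\t1e-1\t0.01\t5E-2\t0.02"))
  d <- read_mr_dataset(path)
  expect_equal(d$variants$beta_exposure, 0.1)
  expect_equal(d$variants$beta_outcome, 0.05)
})

test_that("schema and validation errors name the offending column or row", {
  base <- c("variant,beta_exposure,se_exposure,beta_outcome,se_outcome")
  expect_error(
    read_mr_dataset(write_csv_fixture(
      c("variant,beta_exposure,se_exposure,beta_outcome",
        "rs1,0.1,0.01,0.05"))),
    "se_outcome")
  expect_error(
    read_mr_dataset(write_csv_fixture(
      c(base, "rs1,0.1,0.01,0.05,0.02", "rs2,0.2,0.02,0.06,0.02",
        "rs3,0.1,0,0.05,0.02"))),
    "row 3")
  expect_error(
    read_mr_dataset(write_csv_fixture(
      c(base, "rs1,0.1,0.01,0.05,0.02", "rs1,0.2,0.02,0.06,0.02"))),
    "duplicate")
  expect_error(
    read_mr_dataset(write_csv_fixture(
      c(base, "rs1,0.1,0.01,oops,0.02"))),
    "non-numeric")
  expect_error(mr_dataset("rs1", 0.1, 0.01, Inf, 0.02), "non-finite")
})

test_that("unmapped columns (e.g. alleles) are echoed through unchanged", {
  path <- write_csv_fixture(
    c("variant,beta_exposure,se_exposure,beta_outcome,se_outcome,ea,oa",
      "rs1,0.1,0.01,0.05,0.02,A,G"))
  d <- read_mr_dataset(path)
  expect_equal(d$variants$ea, "A")
  out <- tempfile(fileext = ".csv")
  write_mr_dataset(d, out)
  expect_equal(read_mr_dataset(out)$variants$oa, "G")
})

test_that("orientation flips negative-exposure variants jointly and is idempotent", {
  d <- mr_dataset(c("a", "b"), c(-0.1, 0.2), c(0.01, 0.02),
                  c(0.05, -0.08), c(0.02, 0.03),
                  covariates = cbind(c(-0.3, 0.4)))
  o <- orient_exposure(d)
  expect_true(o$oriented)
  expect_equal(o$variants$beta_exposure, c(0.1, 0.2))
  expect_equal(o$variants$beta_outcome, c(-0.05, -0.08))
  expect_equal(o$variants$beta_exposure2, c(0.3, 0.4))
  expect_equal(o$variants$se_exposure, d$variants$se_exposure)
  expect_identical(orient_exposure(o), o)
})

test_that("zero exposure association makes orientation (and ratios) an error", {
  d <- mr_dataset(c("a", "b"), c(0, 0.2), c(0.01, 0.02),
                  c(0.05, -0.08), c(0.02, 0.03))
  expect_error(orient_exposure(d), "exactly 0")
  expect_error(ratio_estimates(d), "orient")
})

test_that("read -> write -> read round-trips the numeric representation", {
  d <- rand_dataset(9, seed = 11, signs = TRUE)
  p1 <- tempfile(fileext = ".csv")
  write_mr_dataset(d, p1)
  d2 <- read_mr_dataset(p1)
  expect_equal(d2$variants, d$variants)
  p2 <- tempfile(fileext = ".csv")
  write_mr_dataset(d2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("every downstream estimate is invariant to joint per-variant sign flips", {
  d <- rand_dataset(8, seed = 21)
  for (i in c(2L, 5L)) {
    flipped <- d
    flipped$variants$beta_exposure[i] <- -flipped$variants$beta_exposure[i]
    flipped$variants$beta_outcome[i] <- -flipped$variants$beta_outcome[i]
    expect_equal(mr_ivw(flipped)$beta, mr_ivw(d)$beta)
    expect_equal(mr_egger(flipped)$beta, mr_egger(d)$beta)
    expect_equal(cochran_q(flipped)$Q, cochran_q(d)$Q)
    expect_equal(mr_weighted_median(flipped, n_boot = 5, seed = 1)$beta,
                 mr_weighted_median(d, n_boot = 5, seed = 1)$beta)
  }
})
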