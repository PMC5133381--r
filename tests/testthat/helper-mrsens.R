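# Fixture builders used throughout the suite. Everything is generated in
# code under fixed seeds; no binary fixtures.

# dataset with prescribed per-variant ratio estimates and first-order SEs:
# beta_exposure = 1 makes theta == beta_outcome and se(theta) == se_outcome
dataset_from_ratios <- function(theta, se, se_exposure = 1e-4, ...) {
  J <- length(theta)
  mr_dataset(sprintf("v%02d", seq_len(J)), rep(1, J),
             rep_len(se_exposure, J), theta, se, ...)
}

# random but valid dataset; `signs` mixes in negative exposure associations
rand_dataset <- function(J, seed, signs = FALSE) {
  with_seed_test(seed, {
    s <- if (signs) sample(c(-1, 1), J, replace = TRUE) else rep(1, J)
    mr_dataset(sprintf("v%02d", seq_len(J)),
               s * stats::runif(J, 0.05, 0.2),
               stats::runif(J, 0.003, 0.01),
               s * stats::rnorm(J, 0, 0.05),
               stats::runif(J, 0.01, 0.05))
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# independent brute-force oracle for the weighted median: the median of a
# discrete empirical distribution holding `copies` draws of theta in
# proportion to the weights
discrete_median_oracle <- function(theta, w, copies = 1e6) {
  stats::median(rep(theta, round(w / sum(w) * copies)))
}

write_csv_fixture <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
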