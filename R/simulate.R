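# Synthetic two-sample summarized MR data with known truth, and Monte-Carlo
# estimation of estimator operating characteristics under configurable
# pleiotropy architectures.

#' Configure the summarized-data simulator
#'
#' Defines the generating model for synthetic two-sample MR summary data.
#' Per variant j: a true instrument strength gamma_j ~ Uniform(gamma_range);
#' a direct (pleiotropic) effect alpha_j, zero for valid variants; the true
#' outcome association Gamma_j = theta * gamma_j + alpha_j; and observed
#' associations beta_exposure_j ~ N(gamma_j, se_exposure^2),
#' beta_outcome_j ~ N(Gamma_j, se_outcome^2) drawn independently (the
#' two-sample structure). The first `ceiling(J * invalid_fraction)` variants
#' are the invalid ones; the truth record always identifies them.
#'
#' Pleiotropy architectures for the invalid variants:
#' \describe{
#'   \item{none}{all alpha_j = 0 (`invalid_fraction` forced to 0).}
#'   \item{balanced}{alpha_j ~ N(0, pleiotropy_scale^2): direct effects
#'     average to zero, satisfying InSIDE; they add heterogeneity but no
#'     directional bias.}
#'   \item{directional}{alpha_j ~ Uniform(0, pleiotropy_scale): direct
#'     effects share a sign (mean pleiotropy_scale/2), biasing weight-based
#'     estimators; InSIDE still holds as alpha is independent of gamma.}
#'   \item{inside_violated}{alpha_j = inside_correlation * (gamma_j -
#'     mean(gamma_range)) * pleiotropy_scale + N(0, (pleiotropy_scale/2)^2):
#'     direct effects correlated with instrument strength, violating InSIDE
#'     and biasing the Egger slope in the direction of the correlation.}
#' }
#'
#' Defaults emulate a large-GWAS biomarker setting of the kind the package
#' is aimed at: 17 independent variants with per-allele effects of
#' 0.05--0.15 on a log-transformed exposure measured with se 0.005, and
#' log odds-ratio outcome associations with se 0.03.
#'
#' @param J number of variants (>= 2).
#' @param theta true causal effect (outcome units per exposure unit).
#' @param gamma_range length-2 positive range for the uniform instrument
#'   strengths (positive, so the generated data are oriented by
#'   construction up to sampling noise).
#' @param se_exposure,se_outcome sampling SDs of the observed associations;
#'   scalars or length-J vectors; non-negative (0 gives the noise-free
#'   limit).
#' @param invalid_fraction fraction of variants given pleiotropic effects.
#' @param pleiotropy architecture, see above.
#' @param pleiotropy_scale non-negative scale of the direct effects.
#' @param inside_correlation in `[-1, 1]`, used by `inside_violated`.
#' @param seed integer seed used by [simulate_mr_dataset()] by default.
#' @return a validated list of class `mr_sim_config`.
#' @export
mr_sim_config <- function(J = 17, theta = 0, gamma_range = c(0.05, 0.15),
                          se_exposure = 0.005, se_outcome = 0.03,
                          invalid_fraction = 0,
                          pleiotropy = c("none", "balanced", "directional",
                                         "inside_violated"),
                          pleiotropy_scale = 0, inside_correlation = 0,
                          seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  if (J < 2) stop("config error: J must be >= 2")
  if (length(gamma_range) != 2 || gamma_range[1] <= 0 ||
      gamma_range[2] < gamma_range[1])
    stop("config error: gamma_range must be an increasing positive pair")
  if (any(se_exposure < 0) || any(se_outcome < 0))
    stop("config error: sampling SDs must be non-negative")
  if (invalid_fraction < 0 || invalid_fraction > 1)
    stop("config error: invalid_fraction must be in [0, 1]")
  if (pleiotropy_scale < 0)
    stop("config error: pleiotropy_scale must be non-negative")
  if (abs(inside_correlation) > 1)
    stop("config error: inside_correlation must be in [-1, 1]")
  if (pleiotropy == "none") invalid_fraction <- 0
  structure(list(J = as.integer(J), theta = theta,
                 gamma_range = gamma_range,
                 se_exposure = rep_len(se_exposure, J),
                 se_outcome = rep_len(se_outcome, J),
                 invalid_fraction = invalid_fraction,
                 pleiotropy = pleiotropy,
                 pleiotropy_scale = pleiotropy_scale,
                 inside_correlation = inside_correlation,
                 seed = as.integer(seed)),
            class = "mr_sim_config")
}

#' Simulate one two-sample summarized dataset with known truth
#'
#' @param config an [mr_sim_config()].
#' @param seed overrides `config$seed` for this draw.
#' @return a list with `data` (an un-oriented `mr_dataset`) and `truth`
#'   (data.frame: `variant`, `gamma`, `alpha`, `Gamma`, `valid`).
#' @export
simulate_mr_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "mr_sim_config"))
  with_seed(seed, {
    J <- config$J
    gamma <- stats::runif(J, config$gamma_range[1], config$gamma_range[2])
    alpha <- numeric(J)
    n_invalid <- ceiling(J * config$invalid_fraction)
    if (n_invalid > 0) {
      idx <- seq_len(n_invalid)
      s <- config$pleiotropy_scale
      alpha[idx] <- switch(config$pleiotropy,
        balanced = stats::rnorm(n_invalid, 0, s),
        directional = stats::runif(n_invalid, 0, s),
        inside_violated = config$inside_correlation *
          (gamma[idx] - mean(config$gamma_range)) * s +
          stats::rnorm(n_invalid, 0, s / 2),
        numeric(n_invalid))
    }
    Gamma <- config$theta * gamma + alpha
    bx <- stats::rnorm(J, gamma, config$se_exposure)
    by <- stats::rnorm(J, Gamma, config$se_outcome)
    ids <- sprintf("snp_%03d", seq_len(J))
    # observed SEs: the sampling SDs (0 in the noise-free limit would break
    # the positivity invariant, so floor at a tiny positive value)
    sex <- pmax(config$se_exposure, 1e-12)
    sey <- pmax(config$se_outcome, 1e-12)
    list(data = mr_dataset(ids, bx, sex, by, sey,
                           exposure_label = "simulated exposure",
                           outcome_label = "simulated outcome"),
         truth = data.frame(variant = ids, gamma = gamma, alpha = alpha,
                            Gamma = Gamma,
                            valid = seq_len(J) > n_invalid,
                            stringsAsFactors = FALSE))
  })
}

#' Monte-Carlo operating characteristics of an estimator
#'
#' Repeatedly simulates datasets under `config`, applies one estimator, and
#' summarises its behaviour: rejection rate of the two-sided test at level
#' `alpha` (type-I error when `config$theta == 0`, power otherwise), mean
#' estimate, bias, RMSE, and the binomial Monte-Carlo standard error of the
#' rejection rate. Replicate r uses seed `seed + r` for the data draw (and,
#' for the median estimators, for their bootstrap unless a `seed` is passed
#' through `...`), so any single replicate can be regenerated in isolation
#' via `simulate_mr_dataset(config, seed + r)`.
#'
#' @param config an [mr_sim_config()].
#' @param method estimator name, see [mr_estimate()].
#' @param n_sims number of replicates.
#' @param alpha test level for the rejection rate.
#' @param seed master seed (replicate r uses `seed + r`).
#' @param ... passed to the estimator (e.g. `model`, `n_boot`).
#' @return a list of class `mr_oc`: `method`, `n_sims`, `n_failed`,
#'   `rejection_rate`, `mean_estimate`, `bias`, `rmse`, `mc_se` (of the
#'   rejection rate), `mc_se_mean` (of the mean estimate), and the
#'   per-replicate `betas` and `p_values`. Replicates on which the
#'   estimator errors are counted in `n_failed` and excluded from the
#'   averages.
#' @export
operating_characteristics <- function(config, method = "ivw",
                                      n_sims = 500, alpha = 0.05,
                                      seed = config$seed, ...) {
  stopifnot(inherits(config, "mr_sim_config"))
  if (n_sims < 1) stop("n_sims must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  dots <- list(...)
  seed_boot <- grepl("median", method) && is.null(dots$seed)
  betas <- p_values <- rep(NA_real_, n_sims)
  for (r in seq_len(n_sims)) {
    sim <- simulate_mr_dataset(config, seed = seed + r)
    args <- c(list(sim$data, method), dots)
    if (seed_boot) args$seed <- seed + r
    fit <- tryCatch(do.call(mr_estimate, args),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      betas[r] <- fit$beta
      p_values[r] <- fit$p_value
    }
  }
  ok <- !is.na(betas)
  n_ok <- sum(ok)
  rej <- mean(p_values[ok] < alpha)
  bias <- mean(betas[ok]) - config$theta
  structure(list(method = method, n_sims = n_sims,
                 n_failed = n_sims - n_ok,
                 rejection_rate = rej,
                 mean_estimate = mean(betas[ok]), bias = bias,
                 rmse = sqrt(mean((betas[ok] - config$theta)^2)),
                 mc_se = sqrt(rej * (1 - rej) / n_ok),
                 mc_se_mean = stats::sd(betas[ok]) / sqrt(n_ok),
                 alpha = alpha, theta = config$theta, seed = seed,
                 betas = betas, p_values = p_values),
            class = "mr_oc")
}

#' @export
print.mr_oc <- function(x, digits = 4, ...) {
  cat(sprintf("Operating characteristics: %s, %d replicates (theta = %g)\n",
              x$method, x$n_sims, x$theta))
  cat(sprintf(
    "  rejection rate %.3f (mc se %.3f) at alpha = %g\n  mean estimate %s, bias %s, rmse %s\n",
    x$rejection_rate, x$mc_se, x$alpha, signif(x$mean_estimate, digits),
    signif(x$bias, digits), signif(x$rmse, digits)))
  if (x$n_failed > 0)
    cat(sprintf("  failed replicates: %d (excluded)\n", x$n_failed))
  invisible(x)
}
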