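# Causal-effect estimators for two-sample summarized MR data.
#
# All estimators orient the dataset first (joint sign-flip invariance), and
# all share the mr_fit result container. Fixed-effect and multiplicative
# random-effects flavors always share the point estimate; the random model
# inflates standard errors by sqrt(phi), phi = max(1, Q_resid / resid df),
# truncated below at 1 so the random model is never narrower than the fixed.

new_mr_fit <- function(method, model, beta, se, p_value = NULL,
                       n_variants, conf_level = 0.95, dispersion = NULL,
                       intercept = NULL, df_ci = Inf, dataset = NULL,
                       extra = list()) {
  q <- ci_quantile(conf_level, df_ci)
  if (is.null(p_value)) p_value <- p_from_z(beta / se, df_ci)
  out <- c(list(method = method, model = model, beta = beta, se = se,
                ci_low = beta - q * se, ci_high = beta + q * se,
                p_value = p_value, n_variants = n_variants,
                conf_level = conf_level, dispersion = dispersion,
                intercept = intercept,
                outcome_scale = if (!is.null(dataset)) dataset$outcome_scale,
                exposure_sd = if (!is.null(dataset)) dataset$exposure_sd),
           extra)
  class(out) <- "mr_fit"
  out
}

# CI multiplier and two-sided p; df = Inf gives the normal approximation
ci_quantile <- function(conf_level, df = Inf) {
  if (is.finite(df)) stats::qt(1 - (1 - conf_level) / 2, df = df)
  else stats::qnorm(1 - (1 - conf_level) / 2)
}

p_from_z <- function(z, df = Inf) {
  if (is.finite(df)) 2 * stats::pt(-abs(z), df = df)
  else 2 * stats::pnorm(-abs(z))
}

#' Inverse-variance weighted (IVW) estimate
#'
#' Precision-weighted average of the per-variant ratio estimates,
#' beta = sum(w_j theta_j) / sum(w_j) with w_j = se(theta_j)^-2. With
#' first-order ratio SEs this is identical to the weighted least-squares
#' regression of the outcome associations on the exposure associations
#' through the origin, with weights se_outcome^-2. The fixed-effect model
#' takes se = (sum w_j)^-1/2; the multiplicative random-effects model keeps
#' the same point estimate and inflates the SE by sqrt(phi) with
#' phi = max(1, Q/(J-1)), Q being Cochran's heterogeneity statistic.
#'
#' @param data an `mr_dataset` (oriented automatically).
#' @param model `"fixed"` or `"random"` (multiplicative random-effects).
#' @param se_method ratio SE order, see [ratio_estimates()].
#' @param conf_level confidence level for the reported interval.
#' @return an object of class `mr_fit`.
#' @export
#' @examples
#' d <- mr_dataset(paste0("rs", 1:3), c(.1, .2, .15), c(.01, .01, .01),
#'                 c(.05, .09, .08), c(.02, .02, .02))
#' mr_ivw(d)
mr_ivw <- function(data, model = c("fixed", "random"),
                   se_method = c("first", "second"), conf_level = 0.95) {
  model <- match.arg(model)
  data <- orient_exposure(data)
  r <- ratio_estimates(data, se_method = se_method)
  J <- nrow(r)
  if (model == "random" && J < 2L)
    stop("the multiplicative random-effects model needs at least 2 ",
         "variants (the dispersion is undefined for J = 1)")
  beta <- sum(r$weight * r$theta) / sum(r$weight)
  se_fixed <- sum(r$weight)^-0.5
  dispersion <- 1
  if (model == "random") {
    Q <- sum(r$weight * (r$theta - beta)^2)
    dispersion <- max(1, Q / (J - 1))
  }
  new_mr_fit("ivw", model, beta, se_fixed * sqrt(dispersion),
             n_variants = J, conf_level = conf_level,
             dispersion = dispersion, dataset = data)
}

#' Egger regression estimate and intercept test
#'
#' Weighted least-squares regression of the outcome associations on the
#' exposure associations with an intercept, weights se_outcome^-2, on data
#' oriented so all exposure associations are positive. The slope estimates
#' the causal effect under the InSIDE assumption (pleiotropic direct effects
#' independent of instrument strength); the intercept estimates the average
#' pleiotropic effect of a variant, and its test against zero is the test
#' for directional pleiotropy. The multiplicative random-effects model
#' inflates both SEs by sqrt(phi_E), phi_E = max(1, Q_E/(J-2)) with Q_E the
#' weighted residual sum of squares.
#'
#' The method needs spread in instrument strength: with all exposure
#' associations equal the slope and intercept are not separately identified.
#'
#' @inheritParams mr_ivw
#' @param ci_dist `"normal"` (default) or `"t"`; with `"t"`, confidence
#'   intervals and p-values use a t distribution on J-2 df.
#' @return an `mr_fit` whose `intercept` element holds the intercept
#'   estimate, SE, CI and two-sided p-value.
#' @export
mr_egger <- function(data, model = c("fixed", "random"),
                     conf_level = 0.95, ci_dist = c("normal", "t")) {
  model <- match.arg(model)
  ci_dist <- match.arg(ci_dist)
  data <- orient_exposure(data)
  v <- data$variants
  J <- nrow(v)
  if (J < 3L)
    stop("Egger regression needs at least 3 variants; got ", J)
  if (stats::var(v$beta_exposure) == 0)
    stop("Egger regression is not identified: all exposure associations ",
         "are equal, so there is no spread in instrument strength")
  w <- v$se_outcome^-2
  fit <- stats::lm(beta_outcome ~ beta_exposure, data = v, weights = w)
  cf <- stats::coef(fit)
  Q_E <- sum(w * stats::residuals(fit)^2)
  # fixed-effect (known-variance) standard errors from (X'WX)^-1 directly
  X <- cbind(1, v$beta_exposure)
  se_fixed <- sqrt(diag(chol2inv(chol(crossprod(X * sqrt(w))))))
  dispersion <- if (model == "random") max(1, Q_E / (J - 2)) else 1
  se <- se_fixed * sqrt(dispersion)
  df_ci <- if (ci_dist == "t") J - 2 else Inf
  q <- ci_quantile(conf_level, df_ci)
  intercept <- list(estimate = unname(cf[1L]), se = se[1L],
                    ci_low = unname(cf[1L]) - q * se[1L],
                    ci_high = unname(cf[1L]) + q * se[1L],
                    p_value = p_from_z(cf[1L] / se[1L], df_ci))
  new_mr_fit("egger", model, unname(cf[2L]), unname(se[2L]),
             n_variants = J, conf_level = conf_level,
             dispersion = dispersion, intercept = intercept,
             df_ci = df_ci, dataset = data,
             extra = list(residual_q = Q_E))
}

# Weighted median of estimates `theta` with weights `w`: sort ascending
# (ties broken by `ids` for reproducibility), normalize the weights, form
# cumulative midpoints S_j = sum_{k<=j} w'_k - w'_j/2, and interpolate
# linearly between the bracketing theta values where S crosses 1/2.
weighted_median_interp <- function(theta, w, ids = seq_along(theta)) {
  ord <- order(theta, ids)
  th <- theta[ord]
  wn <- w[ord] / sum(w)
  S <- cumsum(wn) - wn / 2
  n <- length(th)
  if (S[1L] >= 0.5) return(th[1L])
  if (S[n] <= 0.5) return(th[n])
  k <- max(which(S < 0.5))
  th[k] + (0.5 - S[k]) / (S[k + 1L] - S[k]) * (th[k + 1L] - th[k])
}

# Parametric-bootstrap SE for the (weighted) median: per variant, resample
# beta_exposure* ~ N(beta_exposure, se_exposure) and beta_outcome* ~
# N(beta_outcome, se_outcome) independently (two-sample structure),
# recompute ratio estimates, weights and the median per replicate.
boot_median <- function(data, weighted, n_boot, seed,
                        se_method = c("first", "second")) {
  se_method <- match.arg(se_method)
  v <- data$variants
  J <- nrow(v)
  run <- function() {
    bx <- matrix(stats::rnorm(J * n_boot, v$beta_exposure, v$se_exposure),
                 nrow = J)
    by <- matrix(stats::rnorm(J * n_boot, v$beta_outcome, v$se_outcome),
                 nrow = J)
    theta <- by / bx
    se <- switch(se_method,
      first = v$se_outcome / abs(bx),
      second = sqrt(v$se_outcome^2 / bx^2 +
                    by^2 * v$se_exposure^2 / bx^4))
    vapply(seq_len(n_boot), function(b) {
      w <- if (weighted) se[, b]^-2 else rep(1, J)
      weighted_median_interp(theta[, b], w)
    }, numeric(1))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

median_fit <- function(data, weighted, n_boot, seed, se_method,
                       conf_level, ci_type) {
  data <- orient_exposure(data)
  r <- ratio_estimates(data, se_method = se_method)
  J <- nrow(r)
  if (J < 3L)
    stop("median-based estimators need at least 3 variants; got ", J)
  if (n_boot < 1L) stop("n_boot must be >= 1")
  w <- if (weighted) r$weight else rep(1 / J, J)
  beta <- weighted_median_interp(r$theta, w, r$variant)
  reps <- boot_median(data, weighted, n_boot, seed, se_method)
  se <- stats::sd(reps)
  fit <- new_mr_fit(if (weighted) "weighted_median" else "simple_median",
                    "not_applicable", beta, se, n_variants = J,
                    conf_level = conf_level, dataset = data,
                    extra = list(n_boot = n_boot, seed = seed,
                                 ci_type = ci_type))
  if (ci_type == "percentile") {
    qs <- stats::quantile(reps, c((1 - conf_level) / 2,
                                  1 - (1 - conf_level) / 2),
                          names = FALSE, type = 7)
    fit$ci_low <- qs[1L]
    fit$ci_high <- qs[2L]
  }
  fit
}

#' Simple (unweighted) median estimate
#'
#' Median of the per-variant ratio estimates, each given equal weight. A
#' consistent estimate of the causal effect when more than half of the
#' variants are valid instruments. The standard error comes from a
#' parametric bootstrap of the summary associations (see
#' [mr_weighted_median()]); the default CI is beta +/- z * bootstrap SD.
#'
#' @inheritParams mr_weighted_median
#' @return an `mr_fit`.
#' @export
mr_simple_median <- function(data, n_boot = 1000, seed = NULL,
                             se_method = c("first", "second"),
                             conf_level = 0.95,
                             ci_type = c("normal", "percentile")) {
  median_fit(data, weighted = FALSE, n_boot = n_boot, seed = seed,
             se_method = match.arg(se_method), conf_level = conf_level,
             ci_type = match.arg(ci_type))
}

#' Weighted median estimate
#'
#' Median of the empirical distribution in which each per-variant ratio
#' estimate appears with probability proportional to its inverse variance,
#' so more precise estimates carry more weight. Consistent when valid
#' instruments carry more than 50% of the total weight, even if many
#' individual variants are invalid. Computed by sorting the ratio estimates,
#' forming cumulative weight midpoints, and linearly interpolating where the
#' cumulative weight crosses one half; ties in the ratio estimates are
#' broken by variant id so results are reproducible under permutation.
#'
#' The SE is estimated by parametric bootstrap: the exposure and outcome
#' associations are resampled from normal distributions centred at their
#' estimates with their standard errors (independently, reflecting the
#' two-sample design), and the weighted median recomputed per replicate.
#'
#' @inheritParams mr_ivw
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap; `NULL` uses (and advances)
#'   the current RNG state. A fixed seed gives identical SEs across calls.
#' @param ci_type `"normal"` (beta +/- z * bootstrap SD, default) or
#'   `"percentile"` (bootstrap quantiles).
#' @return an `mr_fit`.
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed = NULL,
                               se_method = c("first", "second"),
                               conf_level = 0.95,
                               ci_type = c("normal", "percentile")) {
  median_fit(data, weighted = TRUE, n_boot = n_boot, seed = seed,
             se_method = match.arg(se_method), conf_level = conf_level,
             ci_type = match.arg(ci_type))
}

#' Multivariable IVW estimate
#'
#' Weighted least-squares regression of the outcome associations on the
#' genetic associations with K exposures jointly (no intercept), weights
#' se_outcome^-2. Each exposure's coefficient estimates its direct causal
#' effect with the others held fixed; with K = 1 (no covariate columns)
#' this reduces exactly to [mr_ivw()]. Additional exposures enter through
#' the `covariates` argument of [mr_dataset()].
#'
#' @inheritParams mr_ivw
#' @return an object of class `mr_mvfit`: coefficient, SE, CI and p-value
#'   per exposure, with `coef()` and `confint()` methods.
#' @export
mr_mvivw <- function(data, model = c("fixed", "random"), conf_level = 0.95) {
  model <- match.arg(model)
  data <- orient_exposure(data)
  v <- data$variants
  xcols <- c("beta_exposure", data$covariate_cols)
  K <- length(xcols)
  J <- nrow(v)
  if (J <= K)
    stop("multivariable IVW needs more variants than exposures (J > K); ",
         "J = ", J, ", K = ", K)
  X <- as.matrix(v[, xcols, drop = FALSE])
  if (qr(X)$rank < K)
    stop("exposure-association matrix is rank deficient; the exposures ",
         "are collinear across variants")
  w <- v$se_outcome^-2
  fit <- stats::lm.wfit(x = X, y = v$beta_outcome, w = w)
  Q <- sum(w * fit$residuals^2)
  XtWX_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
  se_fixed <- sqrt(diag(XtWX_inv))
  dispersion <- if (model == "random") max(1, Q / (J - K)) else 1
  se <- se_fixed * sqrt(dispersion)
  beta <- unname(fit$coefficients)
  q <- ci_quantile(conf_level)
  out <- structure(list(method = "multivariable_ivw", model = model,
                        exposures = xcols, beta = beta, se = se,
                        ci_low = beta - q * se, ci_high = beta + q * se,
                        p_value = p_from_z(beta / se),
                        n_variants = J, n_exposures = K,
                        dispersion = dispersion, residual_q = Q,
                        conf_level = conf_level),
                   class = "mr_mvfit")
  out
}

#' Fit an MR estimator selected by name
#'
#' Dispatcher used by the robustness and simulation machinery: fits one of
#' the package's estimators on `data`.
#'
#' @inheritParams mr_ivw
#' @param method one of `"ivw"`, `"egger"`, `"simple_median"`,
#'   `"weighted_median"`.
#' @param ... passed to the selected estimator (e.g. `model`, `n_boot`,
#'   `seed`).
#' @return an `mr_fit`.
#' @export
mr_estimate <- function(data, method = c("ivw", "egger", "simple_median",
                                         "weighted_median"), ...) {
  method <- match.arg(method)
  switch(method,
         ivw = mr_ivw(data, ...),
         egger = mr_egger(data, ...),
         simple_median = mr_simple_median(data, ...),
         weighted_median = mr_weighted_median(data, ...))
}

# evaluate `code` under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
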