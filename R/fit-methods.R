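#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  lab <- c(ivw = "Inverse-variance weighted", egger = "Egger regression",
           simple_median = "Simple median",
           weighted_median = "Weighted median")[x$method]
  model <- switch(x$model, fixed = " (fixed-effect)",
                  multiplicative_random = , random =
                    " (multiplicative random-effects)", "")
  cat(lab, model, ", ", x$n_variants, " variants\n", sep = "")
  cat(sprintf("  estimate %s  se %s  %d%% CI (%s, %s)  p %s\n",
              signif(x$beta, digits), signif(x$se, digits),
              round(100 * x$conf_level), signif(x$ci_low, digits),
              signif(x$ci_high, digits), format.pval(x$p_value)))
  if (!is.null(x$dispersion) && x$model != "fixed")
    cat(sprintf("  dispersion (variance inflation) %s\n",
                signif(x$dispersion, digits)))
  if (!is.null(x$intercept))
    cat(sprintf(
      "  intercept %s  se %s  p %s  (test for directional pleiotropy)\n",
      signif(x$intercept$estimate, digits), signif(x$intercept$se, digits),
      format.pval(x$intercept$p_value)))
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  if (is.null(object$intercept)) c(beta = object$beta)
  else c(intercept = object$intercept$estimate, beta = object$beta)
}

#' @export
confint.mr_fit <- function(object, parm, level, ...) {
  m <- matrix(c(object$ci_low, object$ci_high), nrow = 1,
              dimnames = list("beta", c("low", "high")))
  if (!is.null(object$intercept))
    m <- rbind(intercept = c(object$intercept$ci_low,
                             object$intercept$ci_high), m)
  m
}

#' @export
summary.mr_fit <- function(object, ...) {
  print(object, ...)
  invisible(object)
}

#' @export
print.mr_mvfit <- function(x, digits = 4, ...) {
  cat(sprintf("Multivariable IVW (%s), %d variants, %d exposures\n",
              if (x$model == "fixed") "fixed-effect"
              else "multiplicative random-effects",
              x$n_variants, x$n_exposures))
  tab <- data.frame(estimate = signif(x$beta, digits),
                    se = signif(x$se, digits),
                    ci_low = signif(x$ci_low, digits),
                    ci_high = signif(x$ci_high, digits),
                    p = format.pval(x$p_value),
                    row.names = x$exposures)
  print(tab)
  invisible(x)
}

#' @export
coef.mr_mvfit <- function(object, ...) {
  stats::setNames(object$beta, object$exposures)
}

#' @export
confint.mr_mvfit <- function(object, parm, level, ...) {
  matrix(c(object$ci_low, object$ci_high), ncol = 2,
         dimnames = list(object$exposures, c("low", "high")))
}

#' Convert a log-odds estimate to an odds ratio per SD of exposure
#'
#' Rescales a causal estimate on the log odds scale to the odds ratio for a
#' 1-SD increase in the exposure: OR = exp(beta * exposure_sd), with the
#' confidence limits transformed the same (monotone) way. For the CRP
#' example a 1-SD increase equals a 1.05-unit increase in log-transformed
#' concentration, so beta = 1 maps to exp(1.05) = 2.86-fold odds.
#'
#' @param estimate an `mr_fit` from an outcome on the log-odds scale.
#' @param exposure_sd positive scalar, SD of the exposure in the units of
#'   `beta_exposure`; defaults to the value recorded on the dataset.
#' @return a list of class `mr_or` with elements `or`, `ci_low`, `ci_high`,
#'   `conf_level` and the source method/model.
#' @export
to_odds_ratio <- function(estimate, exposure_sd = NULL) {
  stopifnot(inherits(estimate, "mr_fit"))
  if (!identical(estimate$outcome_scale, "log_odds"))
    stop("odds-ratio conversion needs an outcome on the log-odds scale; ",
         "this estimate's outcome scale is '", estimate$outcome_scale, "'")
  if (is.null(exposure_sd)) exposure_sd <- estimate$exposure_sd
  if (is.null(exposure_sd) || !is.numeric(exposure_sd) || exposure_sd <= 0)
    stop("exposure_sd must be a positive number (give it here or record ",
         "it on the dataset)")
  structure(list(or = exp(estimate$beta * exposure_sd),
                 ci_low = exp(estimate$ci_low * exposure_sd),
                 ci_high = exp(estimate$ci_high * exposure_sd),
                 conf_level = estimate$conf_level,
                 method = estimate$method, model = estimate$model,
                 exposure_sd = exposure_sd),
            class = "mr_or")
}

#' @export
print.mr_or <- function(x, digits = 3, ...) {
  cat(sprintf("OR per %g-unit (1 SD) increase: %s (%d%% CI %s, %s)  [%s, %s]\n",
              x$exposure_sd, signif(x$or, digits),
              round(100 * x$conf_level), signif(x$ci_low, digits),
              signif(x$ci_high, digits), x$method, x$model))
  invisible(x)
}
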