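#' Cochran's Q test for heterogeneity of the ratio estimates
#'
#' A statistical assessment of whether the per-variant causal estimates are
#' mutually compatible, i.e. whether all variants identify the same causal
#' parameter. With theta_j the ratio estimates, w_j their inverse-variance
#' weights and theta_IVW the fixed-effect pooled estimate,
#' Q = sum_j w_j (theta_j - theta_IVW)^2, referred to a chi-squared
#' distribution with J-1 degrees of freedom under homogeneity. Excess
#' heterogeneity (Q much larger than its df) suggests that some variants are
#' not valid instruments. The I^2 statistic, max(0, (Q - df)/Q), expresses
#' the proportion of variability beyond chance. Per-variant contributions
#' q_j = w_j (theta_j - theta_IVW)^2 localise the heterogeneity and drive
#' [prune_outliers()].
#'
#' @inheritParams mr_ivw
#' @return an object of class `mr_het`: `Q`, `df`, `p_value`, `i_squared`
#'   (fraction in `[0, 1]`), and `contributions` (data.frame `variant`, `q`).
#' @export
#' @examples
#' d <- mr_dataset(c("a", "b"), c(.1, .1), c(.01, .01), c(.1, .2), c(.1, .1))
#' cochran_q(d)
cochran_q <- function(data, se_method = c("first", "second")) {
  data <- orient_exposure(data)
  r <- ratio_estimates(data, se_method = match.arg(se_method))
  J <- nrow(r)
  if (J < 2L) stop("Cochran's Q needs at least 2 variants")
  beta_ivw <- sum(r$weight * r$theta) / sum(r$weight)
  q_j <- r$weight * (r$theta - beta_ivw)^2
  Q <- sum(q_j)
  structure(list(Q = Q, df = J - 1L,
                 p_value = stats::pchisq(Q, df = J - 1L, lower.tail = FALSE),
                 i_squared = if (Q == 0) 0 else max(0, (Q - (J - 1L)) / Q),
                 ivw_beta = beta_ivw,
                 contributions = data.frame(variant = r$variant, q = q_j,
                                            stringsAsFactors = FALSE)),
            class = "mr_het")
}

#' @export
print.mr_het <- function(x, digits = 4, ...) {
  cat(sprintf("Cochran's Q = %s on %d df, p = %s, I^2 = %.1f%%\n",
              signif(x$Q, digits), x$df, format.pval(x$p_value),
              100 * x$i_squared))
  invisible(x)
}

#' Remove variants with outlying heterogeneity contributions
#'
#' Omits variants whose contribution to Cochran's Q exceeds a threshold,
#' by default the upper 95th percentile of a chi-squared distribution on one
#' degree of freedom (3.84). The default single pass computes all
#' contributions once on the full dataset and removes every offender;
#' iterative mode instead repeatedly removes the single largest offender and
#' recomputes, which can uncover co-outliers that mask each other but may
#' remove more variants.
#'
#' @param data an `mr_dataset` with at least 3 variants.
#' @param threshold contribution cutoff; default `qchisq(0.95, df = 1)`.
#' @param iterative logical, see above.
#' @param se_method ratio SE order, see [ratio_estimates()].
#' @return a list with `data` (the pruned `mr_dataset`) and `removed`
#'   (character vector of removed variant ids, in removal order).
#' @section Errors: pruning that would leave fewer than 2 variants is an
#'   error reporting the removal trail.
#' @export
prune_outliers <- function(data, threshold = stats::qchisq(0.95, df = 1),
                           iterative = FALSE,
                           se_method = c("first", "second")) {
  se_method <- match.arg(se_method)
  data <- orient_exposure(data)
  if (n_variants(data) < 3L)
    stop("outlier pruning needs at least 3 variants")
  removed <- character(0)
  if (!iterative) {
    het <- cochran_q(data, se_method = se_method)
    bad <- het$contributions$q > threshold
    removed <- het$contributions$variant[bad]
    if (n_variants(data) - length(removed) < 2L)
      stop("pruning would leave fewer than 2 variants; removal trail: ",
           paste(removed, collapse = ", "))
    if (length(removed))
      data <- subset_variants(data, !data$variants$variant %in% removed)
  } else {
    repeat {
      if (n_variants(data) < 3L) break
      het <- cochran_q(data, se_method = se_method)
      worst <- which.max(het$contributions$q)
      if (het$contributions$q[worst] <= threshold) break
      removed <- c(removed, het$contributions$variant[worst])
      data <- subset_variants(data, -worst)
    }
  }
  list(data = data, removed = removed)
}

#' Test for directional pleiotropy (Egger intercept)
#'
#' Named wrapper around the intercept block of [mr_egger()]: under the
#' InSIDE assumption the Egger intercept estimates the average pleiotropic
#' effect of a variant, and an intercept differing from zero is evidence of
#' directional (unbalanced) pleiotropy. The default uses the multiplicative
#' random-effects model, so residual heterogeneity among the variants is
#' absorbed into the intercept's standard error, and t-distribution
#' inference on J-2 df: with the dispersion estimated from the weighted
#' residuals this is exactly the weighted-least-squares t-test of the
#' intercept, which holds its nominal level under balanced pleiotropy where
#' the normal approximation over-rejects at small J.
#'
#' @inheritParams mr_egger
#' @return a list of class `mr_pleio_test`: `estimate`, `se`, `ci_low`,
#'   `ci_high`, `p_value`, plus the model used and `n_variants`.
#' @export
directional_pleiotropy_test <- function(data, model = c("random", "fixed"),
                                        conf_level = 0.95,
                                        ci_dist = c("t", "normal")) {
  model <- match.arg(model)
  fit <- mr_egger(data, model = model, conf_level = conf_level,
                  ci_dist = match.arg(ci_dist))
  structure(c(fit$intercept,
              list(model = model, n_variants = fit$n_variants,
                   conf_level = conf_level)),
            class = "mr_pleio_test")
}

#' @export
print.mr_pleio_test <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Test for directional pleiotropy (Egger intercept, %s model)\n",
    x$model))
  cat(sprintf("  intercept %s  se %s  %d%% CI (%s, %s)  p %s\n",
              signif(x$estimate, digits), signif(x$se, digits),
              round(100 * x$conf_level), signif(x$ci_low, digits),
              signif(x$ci_high, digits), format.pval(x$p_value)))
  invisible(x)
}
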