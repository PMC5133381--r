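#' Per-variant ratio (Wald) estimates
#'
#' For each variant j the causal effect of the exposure on the outcome is
#' estimated by the ratio of its outcome association to its exposure
#' association, theta_j = beta_outcome_j / beta_exposure_j. The default
#' standard error is the first-order delta-method approximation
#' se_outcome_j / beta_exposure_j, which treats the exposure association as
#' known; with it, the inverse-variance weighted average of the ratios is
#' exactly the weighted regression of outcome on exposure associations
#' through the origin. The second-order option additionally propagates the
#' exposure-side sampling error:
#' sqrt(se_outcome^2/beta_exposure^2 + beta_outcome^2 se_exposure^2 / beta_exposure^4).
#'
#' @param data an oriented `mr_dataset` (see [orient_exposure()]).
#' @param se_method `"first"` (default) or `"second"` order ratio SE.
#' @return data.frame with columns `variant`, `theta`, `se`, `weight`
#'   (`= se^-2`), one row per variant in dataset order.
#' @export
ratio_estimates <- function(data, se_method = c("first", "second")) {
  se_method <- match.arg(se_method)
  stopifnot(inherits(data, "mr_dataset"))
  v <- data$variants
  if (!isTRUE(data$oriented) || any(v$beta_exposure <= 0))
    stop("ratio estimates require an oriented dataset with all ",
         "beta_exposure > 0; call orient_exposure() first")
  theta <- v$beta_outcome / v$beta_exposure
  se <- switch(se_method,
    first = v$se_outcome / v$beta_exposure,
    second = sqrt(v$se_outcome^2 / v$beta_exposure^2 +
                  v$beta_outcome^2 * v$se_exposure^2 / v$beta_exposure^4))
  data.frame(variant = v$variant, theta = theta, se = se,
             weight = se^-2, stringsAsFactors = FALSE)
}
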