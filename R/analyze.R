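#' Run the full sensitivity-analysis battery on one dataset
#'
#' Orientation, per-variant ratio estimates, IVW (fixed and multiplicative
#' random-effects), Egger regression (both models), simple and weighted
#' medians, Cochran's Q with I^2, the directional-pleiotropy (Egger
#' intercept) test, and optionally a leave-one-out analysis -- collected
#' into a single self-describing report. Methods whose preconditions the
#' dataset does not meet (e.g. Egger with 2 variants) are recorded as not
#' computed rather than failing the run. The report is deterministic for a
#' fixed seed.
#'
#' @param data an `mr_dataset`, or a file path accepted by
#'   [read_mr_dataset()].
#' @param exposure_sd optional positive scalar; if the outcome is on the
#'   log-odds scale, estimates are additionally reported as odds ratios per
#'   SD of exposure.
#' @param alpha significance level used only for the `significant` flag
#'   column (raw p-values are always reported, uncorrected).
#' @param n_boot bootstrap replicates for the median estimators.
#' @param seed integer seed for the bootstrap.
#' @param loo also run [leave_one_out()] with the fixed-effect IVW.
#' @param se_method ratio SE order, see [ratio_estimates()].
#' @param conf_level confidence level throughout.
#' @return a list of class `mr_report`: `dataset` (J and labels),
#'   `estimates` (one row per method/model with status), `heterogeneity`,
#'   `pleiotropy`, optional `leave_one_out` summary, `seed`, `alpha`,
#'   `version`.
#' @export
mr_analyze <- function(data, exposure_sd = NULL, alpha = 0.05,
                       n_boot = 1000, seed = 1, loo = TRUE,
                       se_method = "first", conf_level = 0.95) {
  if (is.character(data)) data <- read_mr_dataset(data)
  stopifnot(inherits(data, "mr_dataset"))
  if (!is.null(exposure_sd)) data$exposure_sd <- exposure_sd
  data <- orient_exposure(data)
  J <- n_variants(data)

  specs <- list(
    list(method = "ivw", model = "fixed"),
    list(method = "ivw", model = "random"),
    list(method = "egger", model = "fixed"),
    list(method = "egger", model = "random"),
    list(method = "simple_median", model = "not_applicable"),
    list(method = "weighted_median", model = "not_applicable"))

  rows <- lapply(specs, function(s) {
    args <- list(data, method = s$method, conf_level = conf_level)
    if (s$method %in% c("ivw", "egger")) {
      args$model <- s$model
      args$se_method <- if (s$method == "ivw") se_method else NULL
    } else {
      args$n_boot <- n_boot
      args$seed <- seed
      args$se_method <- se_method
    }
    args <- args[!vapply(args, is.null, logical(1))]
    fit <- tryCatch(do.call(mr_estimate, args), error = function(e) e)
    if (inherits(fit, "error"))
      return(data.frame(method = s$method, model = s$model,
                        beta = NA_real_, se = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        n_variants = J, intercept = NA_real_,
                        intercept_se = NA_real_, intercept_p = NA_real_,
                        significant = NA,
                        status = paste("not computed:",
                                       conditionMessage(fit)),
                        stringsAsFactors = FALSE))
    data.frame(method = fit$method, model = fit$model, beta = fit$beta,
               se = fit$se, ci_low = fit$ci_low, ci_high = fit$ci_high,
               p_value = fit$p_value, n_variants = fit$n_variants,
               intercept = if (is.null(fit$intercept)) NA_real_
                           else fit$intercept$estimate,
               intercept_se = if (is.null(fit$intercept)) NA_real_
                              else fit$intercept$se,
               intercept_p = if (is.null(fit$intercept)) NA_real_
                             else fit$intercept$p_value,
               significant = fit$p_value < alpha, status = "ok",
               stringsAsFactors = FALSE)
  })
  estimates <- do.call(rbind, rows)

  if (!is.null(data$exposure_sd) && data$outcome_scale == "log_odds") {
    sd <- data$exposure_sd
    estimates$or_per_sd <- exp(estimates$beta * sd)
    estimates$or_ci_low <- exp(estimates$ci_low * sd)
    estimates$or_ci_high <- exp(estimates$ci_high * sd)
  }

  het <- tryCatch(cochran_q(data, se_method = se_method),
                  error = function(e) conditionMessage(e))
  pleio <- tryCatch(directional_pleiotropy_test(data,
                                                conf_level = conf_level),
                    error = function(e) conditionMessage(e))
  loo_sum <- if (loo && J >= 3L)
    leave_one_out(data, method = "ivw", model = "fixed") else NULL

  structure(list(
    dataset = list(n_variants = J, exposure = data$exposure_label,
                   outcome = data$outcome_label,
                   outcome_scale = data$outcome_scale,
                   exposure_sd = data$exposure_sd),
    estimates = estimates,
    heterogeneity = het,
    pleiotropy = pleio,
    leave_one_out = loo_sum,
    alpha = alpha, seed = seed, n_boot = n_boot,
    se_method = se_method, conf_level = conf_level,
    version = as.character(utils::packageVersion("mrsens"))),
    class = "mr_report")
}

#' @export
print.mr_report <- function(x, digits = 4, ...) {
  cat(sprintf("MR sensitivity-analysis report: %s -> %s (%d variants)\n\n",
              x$dataset$exposure, x$dataset$outcome, x$dataset$n_variants))
  tab <- x$estimates
  show <- c("method", "model", "beta", "se", "ci_low", "ci_high",
            "p_value", intersect("or_per_sd", names(tab)), "status")
  tab[c("beta", "se", "ci_low", "ci_high", "p_value")] <-
    lapply(tab[c("beta", "se", "ci_low", "ci_high", "p_value")],
           signif, digits)
  print(tab[, show], row.names = FALSE)
  cat("\n")
  if (inherits(x$heterogeneity, "mr_het")) print(x$heterogeneity)
  else cat("heterogeneity: not computed:", x$heterogeneity, "\n")
  if (inherits(x$pleiotropy, "mr_pleio_test")) print(x$pleiotropy)
  else cat("directional pleiotropy: not computed:", x$pleiotropy, "\n")
  if (!is.null(x$leave_one_out)) print(x$leave_one_out)
  invisible(x)
}

#' Write a report to JSON (and optionally the estimates table to CSV)
#'
#' The JSON is self-describing (method, model, seed, bootstrap size and
#' package version are all recorded) and byte-identical across runs with
#' the same input and seed.
#'
#' @param report an `mr_report`.
#' @param json_path output JSON path.
#' @param csv_path optional path for the estimates table as CSV.
#' @return `json_path`, invisibly.
#' @export
write_mr_report <- function(report, json_path, csv_path = NULL) {
  stopifnot(inherits(report, "mr_report"))
  out <- report
  class(out) <- NULL
  if (inherits(out$heterogeneity, "mr_het")) {
    h <- out$heterogeneity
    out$heterogeneity <- list(Q = h$Q, df = h$df, p_value = h$p_value,
                              i_squared_percent = 100 * h$i_squared,
                              contributions = h$contributions)
  }
  if (inherits(out$pleiotropy, "mr_pleio_test"))
    out$pleiotropy <- unclass(out$pleiotropy)
  if (!is.null(out$leave_one_out)) {
    l <- out$leave_one_out
    out$leave_one_out <- list(method = l$method, n_subsets = l$n_subsets,
                              n_failed = l$n_failed,
                              fraction_positive = l$fraction_positive,
                              fraction_negative = l$fraction_negative,
                              extremes = l$extremes,
                              estimates = l$estimates)
  }
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  if (!is.null(csv_path))
    utils::write.csv(report$estimates, csv_path, row.names = FALSE)
  invisible(json_path)
}
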