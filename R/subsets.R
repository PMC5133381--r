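# Penalization-by-omission robustness analyses: re-estimate the causal
# effect after omitting subsets of variants, and summarise the spread. If
# the spread of subset estimates lies entirely on one side of the null, the
# overall finding does not hinge on a few (possibly invalid) instruments.

fit_subsets <- function(data, omit_list, method, ...) {
  ids <- data$variants$variant
  rows <- lapply(omit_list, function(om) {
    keep <- setdiff(seq_along(ids), om)
    fit <- tryCatch(mr_estimate(subset_variants(data, keep), method, ...),
                    error = function(e) e)
    if (inherits(fit, "error"))
      data.frame(omitted = paste(ids[om], collapse = ";"),
                 beta = NA_real_, se = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p_value = NA_real_, failed = TRUE,
                 message = conditionMessage(fit), stringsAsFactors = FALSE)
    else
      data.frame(omitted = paste(ids[om], collapse = ";"),
                 beta = fit$beta, se = fit$se, ci_low = fit$ci_low,
                 ci_high = fit$ci_high, p_value = fit$p_value,
                 failed = FALSE, message = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

new_mr_subsets <- function(estimates, mode, method, extra = list()) {
  ok <- estimates[!estimates$failed, , drop = FALSE]
  n_failed <- sum(estimates$failed)
  if (n_failed > 0)
    warning(n_failed, " subset estimate(s) failed and are excluded from ",
            "the spread summaries")
  structure(c(list(estimates = estimates, mode = mode, method = method,
                   n_subsets = nrow(estimates), n_failed = n_failed,
                   fraction_positive = mean(ok$beta > 0),
                   fraction_negative = mean(ok$beta < 0),
                   fraction_zero = mean(ok$beta == 0),
                   extremes = range(ok$beta)),
              extra),
            class = "mr_subsets")
}

#' Leave-one-out analysis
#'
#' Re-estimates the causal effect J times, omitting each variant in turn.
#' An estimate that moves substantially when one variant is dropped flags
#' that variant as influential (and possibly pleiotropic).
#'
#' @param data an `mr_dataset` with at least 3 variants.
#' @param method estimator name, see [mr_estimate()].
#' @param ... passed to the estimator (e.g. `model`, `seed`).
#' @return an object of class `mr_subsets`: per-subset estimates (in
#'   dataset order, `omitted` naming the left-out variants), the fractions
#'   of positive/negative/zero subset estimates among those that succeeded,
#'   and the range of subset estimates. Subsets on which the estimator
#'   errors are flagged `failed`, kept in the table, and excluded from the
#'   fraction summaries with a warning.
#' @export
leave_one_out <- function(data, method = "ivw", ...) {
  stopifnot(inherits(data, "mr_dataset"))
  J <- n_variants(data)
  if (J < 3L) stop("leave-one-out needs at least 3 variants")
  est <- fit_subsets(data, as.list(seq_len(J)), method, ...)
  new_mr_subsets(est, mode = "loo", method = method)
}

#' Systematic leave-k-out analysis
#'
#' Re-estimates the causal effect on every subset formed by omitting k
#' variants, enumerated in lexicographic order -- choose(J, k) estimates in
#' all (136 for J = 17, k = 2). The summary supports the ordered-by-
#' magnitude display of the subset estimates.
#'
#' @inheritParams leave_one_out
#' @param k number of variants omitted per subset.
#' @param cap refuse to enumerate more than this many subsets (default
#'   1e6); use [random_subsets()] beyond it.
#' @return an `mr_subsets` (see [leave_one_out()]).
#' @export
leave_k_out <- function(data, k, method = "ivw", cap = 1e6, ...) {
  stopifnot(inherits(data, "mr_dataset"))
  J <- n_variants(data)
  if (k < 1L) stop("k must be >= 1")
  if (J < k + 2L)
    stop("leave-", k, "-out needs at least k + 2 = ", k + 2L, " variants")
  n_sub <- choose(J, k)
  if (n_sub > cap)
    stop("choose(", J, ", ", k, ") = ", n_sub, " exceeds the cap (", cap,
         "); use random_subsets() for a stochastic version")
  omit <- utils::combn(J, k, simplify = FALSE)
  est <- fit_subsets(data, omit, method, ...)
  new_mr_subsets(est, mode = "lko", method = method, extra = list(k = k))
}

#' Stochastic subset-omission analysis
#'
#' Re-estimates the causal effect on `n_reps` random subsets, each omitting
#' a fixed fraction of the variants chosen uniformly at random without
#' replacement. The number omitted is `round(J * omit_fraction)`
#' (round-half-to-even). Fully reproducible for a fixed seed.
#'
#' @inheritParams leave_one_out
#' @param omit_fraction fraction of variants omitted per replicate, in
#'   (0, 1).
#' @param n_reps number of random subsets.
#' @param seed integer seed.
#' @return an `mr_subsets` (see [leave_one_out()]), with `n_omitted`
#'   recording the per-replicate omission count.
#' @export
random_subsets <- function(data, omit_fraction = 0.3, n_reps = 1000,
                           seed = 1, method = "ivw", ...) {
  stopifnot(inherits(data, "mr_dataset"))
  J <- n_variants(data)
  if (omit_fraction <= 0 || omit_fraction >= 1)
    stop("omit_fraction must be strictly between 0 and 1")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  n_omit <- round(J * omit_fraction)
  min_keep <- switch(method, ivw = 1L, 3L)
  if (J - n_omit < min_keep)
    stop("omitting ", n_omit, " of ", J, " variants leaves too few for ",
         method)
  omit <- with_seed(seed, replicate(n_reps, sample.int(J, n_omit),
                                    simplify = FALSE))
  est <- fit_subsets(data, omit, method, ...)
  new_mr_subsets(est, mode = "random", method = method,
                 extra = list(omit_fraction = omit_fraction,
                              n_omitted = n_omit, seed = seed))
}

#' @export
print.mr_subsets <- function(x, digits = 4, ...) {
  lab <- switch(x$mode, loo = "Leave-one-out",
                lko = sprintf("Systematic leave-%d-out", x$k),
                random = sprintf("Random omission (%g%% per replicate)",
                                 100 * x$omit_fraction))
  cat(sprintf("%s analysis, method = %s: %d subset estimates\n",
              lab, x$method, x$n_subsets))
  if (x$n_failed > 0)
    cat(sprintf("  failed subsets: %d (excluded from summaries)\n",
                x$n_failed))
  cat(sprintf("  estimate range (%s, %s); positive %.1f%%, negative %.1f%%\n",
              signif(x$extremes[1], digits), signif(x$extremes[2], digits),
              100 * x$fraction_positive, 100 * x$fraction_negative))
  invisible(x)
}

#' @export
summary.mr_subsets <- function(object, ...) {
  print(object, ...)
  ok <- object$estimates[!object$estimates$failed, , drop = FALSE]
  print(summary(ok$beta))
  invisible(object)
}
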