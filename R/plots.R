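# Diagnostic displays. Each builder is a pure function returning an
# mr_plotdata object (points + reference lines); rendering with base
# graphics is a thin layer on top, so every number a test asserts comes
# from the plot data, never from a drawn image.

new_plotdata <- function(kind, points, reference_lines, xlab, ylab) {
  structure(list(kind = kind, points = points,
                 reference_lines = reference_lines,
                 xlab = xlab, ylab = ylab),
            class = "mr_plotdata")
}

#' Scatter-plot data: outcome vs exposure associations
#'
#' One point per variant at (beta_exposure, beta_outcome) with symmetric
#' confidence-interval half-widths `q * se` on both axes. Under the causal
#' null with valid instruments the points are compatible with a straight
#' line through the origin; fitted estimators can be overlaid as reference
#' lines -- through the origin with slope beta for IVW, and intercept plus
#' slope for Egger.
#'
#' @param data an `mr_dataset` (oriented automatically).
#' @param fitted optional list of `mr_fit` objects to overlay.
#' @param conf_level level for the error bars (default 0.95 -> 1.96 se).
#' @return an `mr_plotdata`: `points` (x, y, x_err, y_err, label) and
#'   `reference_lines` (orientation "abline" with `intercept`, `slope`).
#' @export
scatter_data <- function(data, fitted = NULL, conf_level = 0.95) {
  data <- orient_exposure(data)
  v <- data$variants
  q <- ci_quantile(conf_level)
  pts <- data.frame(x = v$beta_exposure, y = v$beta_outcome,
                    x_err = q * v$se_exposure, y_err = q * v$se_outcome,
                    label = v$variant, stringsAsFactors = FALSE)
  refs <- data.frame(orientation = character(0), value = numeric(0),
                     intercept = numeric(0), slope = numeric(0),
                     style = character(0), stringsAsFactors = FALSE)
  if (!is.null(fitted)) {
    if (inherits(fitted, "mr_fit")) fitted <- list(fitted)
    refs <- do.call(rbind, lapply(fitted, function(f) {
      data.frame(orientation = "abline", value = NA_real_,
                 intercept = if (is.null(f$intercept)) 0
                             else f$intercept$estimate,
                 slope = f$beta,
                 style = paste(f$method, f$model), stringsAsFactors = FALSE)
    }))
  }
  new_plotdata("scatter", pts, refs,
               xlab = paste("association with", data$exposure_label),
               ylab = paste("association with", data$outcome_label))
}

#' Funnel-plot data: precision vs per-variant causal estimate
#'
#' One point per variant at (theta_j, 1/se(theta_j)): the per-variant ratio
#' estimate against its precision, with horizontal confidence bars on the
#' estimate. Valid instruments give a symmetric funnel -- more precise
#' estimates less spread out; asymmetry about the pooled estimate signals
#' directional pleiotropy. Vertical reference lines mark the null (solid)
#' and the fixed-effect IVW estimate (dashed).
#'
#' @param data an `mr_dataset`.
#' @param ivw_estimate optional `mr_fit` for the dashed line; computed as
#'   the fixed-effect IVW if missing.
#' @param se_method,conf_level as in [ratio_estimates()] / [scatter_data()].
#' @return an `mr_plotdata` with points (x = theta, y = precision,
#'   x_err = q * se, y_err = 0).
#' @export
funnel_data <- function(data, ivw_estimate = NULL,
                        se_method = c("first", "second"),
                        conf_level = 0.95) {
  data <- orient_exposure(data)
  r <- ratio_estimates(data, se_method = match.arg(se_method))
  if (is.null(ivw_estimate)) ivw_estimate <- mr_ivw(data, model = "fixed")
  q <- ci_quantile(conf_level)
  pts <- data.frame(x = r$theta, y = 1 / r$se, x_err = q * r$se,
                    y_err = 0, label = r$variant, stringsAsFactors = FALSE)
  refs <- data.frame(orientation = "vertical",
                     value = c(0, ivw_estimate$beta),
                     intercept = NA_real_, slope = NA_real_,
                     style = c("null (solid)", "ivw (dashed)"),
                     stringsAsFactors = FALSE)
  new_plotdata("funnel", pts, refs,
               xlab = "per-variant causal estimate",
               ylab = "precision (1/se)")
}

#' Ordered subset-estimate data
#'
#' Subset estimates from a robustness analysis ([leave_one_out()],
#' [leave_k_out()], [random_subsets()]) sorted ascending by signed value and
#' plotted against rank, with confidence bars and a horizontal line at the
#' null. Failed subsets are dropped.
#'
#' @param summary an `mr_subsets`.
#' @return an `mr_plotdata` (x = rank, y = beta, y_err = CI half-width).
#' @export
ordered_subsets_data <- function(summary) {
  stopifnot(inherits(summary, "mr_subsets"))
  ok <- summary$estimates[!summary$estimates$failed, , drop = FALSE]
  if (nrow(ok) == 0L) stop("no successful subset estimates to plot")
  ok <- ok[order(ok$beta), , drop = FALSE]
  pts <- data.frame(x = seq_len(nrow(ok)), y = ok$beta, x_err = 0,
                    y_err = (ok$ci_high - ok$ci_low) / 2,
                    label = ok$omitted, stringsAsFactors = FALSE)
  refs <- data.frame(orientation = "horizontal", value = 0,
                     intercept = NA_real_, slope = NA_real_,
                     style = "null", stringsAsFactors = FALSE)
  new_plotdata("ordered_subsets", pts, refs,
               xlab = "subset estimates, ordered by magnitude",
               ylab = "causal estimate")
}

#' @export
plot.mr_plotdata <- function(x, ...) {
  p <- x$points
  graphics::plot(p$x, p$y, pch = 19, xlab = x$xlab, ylab = x$ylab,
                 xlim = range(p$x - p$x_err, p$x + p$x_err),
                 ylim = range(p$y - p$y_err, p$y + p$y_err), ...)
  graphics::segments(p$x - p$x_err, p$y, p$x + p$x_err, p$y)
  graphics::segments(p$x, p$y - p$y_err, p$x, p$y + p$y_err)
  r <- x$reference_lines
  if (nrow(r)) for (i in seq_len(nrow(r))) {
    lty <- if (grepl("dashed|random", r$style[i])) 2L else 1L
    switch(r$orientation[i],
           abline = graphics::abline(a = r$intercept[i], b = r$slope[i],
                                     lty = lty),
           vertical = graphics::abline(v = r$value[i], lty = lty),
           horizontal = graphics::abline(h = r$value[i], lty = lty))
  }
  invisible(x)
}

#' Plot method for summarized MR datasets
#'
#' @param x an `mr_dataset`.
#' @param type `"scatter"` (default) or `"funnel"`.
#' @param fitted optional `mr_fit` overlays for the scatter display.
#' @param ... passed to the base plot call.
#' @return the underlying `mr_plotdata`, invisibly.
#' @export
plot.mr_dataset <- function(x, type = c("scatter", "funnel"),
                            fitted = NULL, ...) {
  type <- match.arg(type)
  pd <- switch(type, scatter = scatter_data(x, fitted = fitted),
               funnel = funnel_data(x))
  plot(pd, ...)
  invisible(pd)
}

#' @export
plot.mr_subsets <- function(x, ...) {
  pd <- ordered_subsets_data(x)
  plot(pd, ...)
  invisible(pd)
}
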