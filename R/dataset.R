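#' Construct a two-sample summarized MR dataset
#'
#' Bundles per-variant summary associations -- the beta-coefficient and
#' standard error of each variant's association with the exposure, and with
#' the outcome -- into a validated container used by every estimator in the
#' package. The two sets of associations are assumed to come from
#' non-overlapping samples (two-sample design), so their sampling errors are
#' independent. Allele harmonization (effect-allele matching, palindromic
#' strand checks) is assumed to have been done upstream; optional allele
#' columns are carried through untouched.
#'
#' @param variant character vector of unique variant identifiers.
#' @param beta_exposure numeric, per-allele association with the exposure.
#' @param se_exposure numeric, standard error of `beta_exposure`; must be
#'   strictly positive.
#' @param beta_outcome numeric, per-allele association with the outcome
#'   (log odds ratio for a binary outcome).
#' @param se_outcome numeric, standard error of `beta_outcome`; strictly
#'   positive.
#' @param covariates optional numeric matrix (or data.frame) of per-allele
#'   associations with additional exposures, one column per exposure, for
#'   multivariable analysis.
#' @param exposure_label,outcome_label human-readable trait names.
#' @param outcome_scale `"log_odds"` (default) or `"linear"`; controls
#'   whether estimates may be exponentiated into odds ratios.
#' @param exposure_sd optional positive scalar: the population SD of the
#'   exposure in the units of `beta_exposure`, used by [to_odds_ratio()] to
#'   rescale estimates to a per-SD basis.
#' @param extra optional data.frame of echoed columns (e.g. alleles), one
#'   row per variant.
#'
#' @return An object of class `mr_dataset`: a list with element `variants`
#'   (a data.frame, one row per variant, in input order), the metadata
#'   fields above, and an `oriented` flag (initially `FALSE`; see
#'   [orient_exposure()]).
#' @seealso [read_mr_dataset()], [orient_exposure()], [mr_ivw()]
#' @export
#' @examples
#' d <- mr_dataset(variant = c("rs1", "rs2"),
#'                 beta_exposure = c(0.1, -0.2), se_exposure = c(0.01, 0.02),
#'                 beta_outcome = c(0.05, -0.08), se_outcome = c(0.02, 0.03))
#' orient_exposure(d)
mr_dataset <- function(variant, beta_exposure, se_exposure,
                       beta_outcome, se_outcome, covariates = NULL,
                       exposure_label = "exposure",
                       outcome_label = "outcome",
                       outcome_scale = c("log_odds", "linear"),
                       exposure_sd = NULL, extra = NULL) {
  outcome_scale <- match.arg(outcome_scale)
  variant <- as.character(variant)
  J <- length(variant)
  if (J < 1L) stop("an mr_dataset needs at least one variant")
  vars <- data.frame(variant = variant,
                     beta_exposure = as.numeric(beta_exposure),
                     se_exposure = as.numeric(se_exposure),
                     beta_outcome = as.numeric(beta_outcome),
                     se_outcome = as.numeric(se_outcome),
                     stringsAsFactors = FALSE)
  covariate_cols <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != J)
      stop("covariates must have one row per variant")
    covariate_cols <- paste0("beta_exposure", seq_len(ncol(covariates)) + 1L)
    colnames(covariates) <- covariate_cols
    vars <- cbind(vars, as.data.frame(covariates))
  }
  if (!is.null(extra)) {
    if (nrow(extra) != J) stop("extra columns must have one row per variant")
    vars <- cbind(vars, extra)
  }
  x <- structure(list(variants = vars,
                      covariate_cols = covariate_cols,
                      exposure_label = exposure_label,
                      outcome_label = outcome_label,
                      outcome_scale = outcome_scale,
                      exposure_sd = exposure_sd,
                      oriented = FALSE),
                 class = "mr_dataset")
  validate_mr_dataset(x)
  x
}

validate_mr_dataset <- function(x) {
  v <- x$variants
  if (anyDuplicated(v$variant))
    stop("duplicate variant_id: ",
         paste(unique(v$variant[duplicated(v$variant)]), collapse = ", "))
  num_cols <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome",
                x$covariate_cols)
  for (cl in num_cols) {
    col <- v[[cl]]
    if (!is.numeric(col))
      stop("column '", cl, "' is not numeric")
    bad <- which(!is.finite(col))
    if (length(bad))
      stop("non-finite value in column '", cl, "' at row ", bad[1L],
           " (variant ", v$variant[bad[1L]], ")")
  }
  for (cl in c("se_exposure", "se_outcome")) {
    bad <- which(v[[cl]] <= 0)
    if (length(bad))
      stop("non-positive standard error in column '", cl, "' at row ",
           bad[1L], " (variant ", v$variant[bad[1L]], ")")
  }
  if (!is.null(x$exposure_sd) &&
      (!is.numeric(x$exposure_sd) || x$exposure_sd <= 0))
    stop("exposure_sd must be a positive number")
  invisible(x)
}

#' Number of variants in a dataset
#' @param data an `mr_dataset`.
#' @return integer count of variants.
#' @export
n_variants <- function(data) {
  stopifnot(inherits(data, "mr_dataset"))
  nrow(data$variants)
}

#' Orient a dataset so all exposure associations are non-negative
#'
#' Every downstream estimator is defined on data oriented to the
#' exposure-increasing allele: for any variant whose exposure association is
#' negative, the signs of its exposure, outcome and covariate
#' beta-coefficients are flipped jointly (equivalent to switching which
#' allele is counted). Standard errors are unchanged. The operation is
#' idempotent, and all estimates in this package are invariant to a joint
#' sign flip of any variant's associations because orientation is applied
#' before estimation.
#'
#' @param data an `mr_dataset`.
#' @return The oriented `mr_dataset` (flag `oriented` set).
#' @section Errors: a variant with `beta_exposure` exactly zero is an error:
#'   its orientation (and its ratio estimate) is undefined. Drop such
#'   variants explicitly before analysis if that is intended.
#' @export
orient_exposure <- function(data) {
  stopifnot(inherits(data, "mr_dataset"))
  if (isTRUE(data$oriented)) return(data)
  v <- data$variants
  zero <- which(v$beta_exposure == 0)
  if (length(zero))
    stop("beta_exposure is exactly 0 for variant ",
         paste(v$variant[zero], collapse = ", "),
         ": orientation (and the ratio estimate) is undefined")
  flip <- v$beta_exposure < 0
  if (any(flip)) {
    for (cl in c("beta_exposure", "beta_outcome", data$covariate_cols))
      v[[cl]][flip] <- -v[[cl]][flip]
    data$variants <- v
  }
  data$oriented <- TRUE
  data
}

# internal: subset variants by index, keeping metadata
subset_variants <- function(data, idx) {
  data$variants <- data$variants[idx, , drop = FALSE]
  rownames(data$variants) <- NULL
  data
}

#' @export
`[.mr_dataset` <- function(x, i, ...) subset_variants(x, i)

#' @export
as.data.frame.mr_dataset <- function(x, ...) x$variants

#' @export
print.mr_dataset <- function(x, ...) {
  cat(sprintf("Two-sample summarized MR dataset: %d variant%s\n",
              n_variants(x), if (n_variants(x) == 1) "" else "s"))
  cat(sprintf("  exposure: %s   outcome: %s (%s scale)\n",
              x$exposure_label, x$outcome_label, x$outcome_scale))
  if (!is.null(x$exposure_sd))
    cat(sprintf("  exposure SD: %g\n", x$exposure_sd))
  cat(sprintf("  oriented to exposure-increasing allele: %s\n",
              if (isTRUE(x$oriented)) "yes" else "no"))
  if (length(x$covariate_cols))
    cat(sprintf("  additional exposures for multivariable analysis: %d\n",
                length(x$covariate_cols)))
  print(utils::head(x$variants, 6L))
  if (n_variants(x) > 6L) cat("  ...\n")
  invisible(x)
}

canonical_cols <- c("variant", "beta_exposure", "se_exposure",
                    "beta_outcome", "se_outcome")

#' Read a summarized-data table from a delimited file
#'
#' Reads a CSV or TSV with a header into an [mr_dataset()]. The canonical
#' column names are `variant, beta_exposure, se_exposure, beta_outcome,
#' se_outcome`, optionally followed by `beta_exposure2, beta_exposure3, ...`
#' for multivariable analysis; `column_map` remaps arbitrary headers onto
#' them. The delimiter is auto-detected between comma and tab unless given.
#' Any unmapped columns (e.g. allele codes) are carried through unchanged.
#'
#' @param path path to the file.
#' @param column_map optional named character vector mapping canonical names
#'   to the file's headers, e.g. `c(variant = "snp", beta_exposure = "bx",
#'   ...)`. Canonical headers need no mapping.
#' @param delim field delimiter; `NULL` (default) auto-detects `,` vs tab.
#' @param ... passed to [mr_dataset()] (labels, scale, `exposure_sd`).
#' @return an un-oriented `mr_dataset`, rows in file order.
#' @export
read_mr_dataset <- function(path, column_map = NULL, delim = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (lengths(regmatches(first, gregexpr("\t", first))) >=
                 lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE)
  # resolve the file header for each canonical column
  resolve <- function(canon) {
    nm <- if (!is.null(column_map) && canon %in% names(column_map))
      unname(column_map[[canon]]) else canon
    if (!nm %in% names(tab))
      stop("schema error: column '", nm, "' (", canon,
           ") not found in ", path)
    nm
  }
  hdr <- vapply(canonical_cols, resolve, character(1))
  k <- 2L
  cov_hdr <- character(0)
  repeat {
    canon <- paste0("beta_exposure", k)
    nm <- if (!is.null(column_map) && canon %in% names(column_map))
      unname(column_map[[canon]]) else canon
    if (!nm %in% names(tab)) break
    cov_hdr <- c(cov_hdr, nm)
    k <- k + 1L
  }
  for (nm in c(hdr[-1L], cov_hdr)) {
    col <- tab[[nm]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop("non-numeric value '", col[bad[1L]], "' in column '", nm,
             "' at row ", bad[1L])
      tab[[nm]] <- num
    }
  }
  extra <- tab[, setdiff(names(tab), c(hdr, cov_hdr)), drop = FALSE]
  mr_dataset(variant = tab[[hdr["variant"]]],
             beta_exposure = tab[[hdr["beta_exposure"]]],
             se_exposure = tab[[hdr["se_exposure"]]],
             beta_outcome = tab[[hdr["beta_outcome"]]],
             se_outcome = tab[[hdr["se_outcome"]]],
             covariates = if (length(cov_hdr)) tab[, cov_hdr, drop = FALSE],
             extra = if (ncol(extra)) extra,
             ...)
}

#' Write a summarized-data table
#'
#' Writes the dataset back out in the same dialect [read_mr_dataset()]
#' accepts (canonical headers), so that read -> write -> read round-trips.
#'
#' @param data an `mr_dataset`.
#' @param path output path.
#' @param delim field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_mr_dataset <- function(data, path, delim = ",") {
  stopifnot(inherits(data, "mr_dataset"))
  utils::write.table(data$variants, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
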