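#' Transform chi-square statistics to z-scores
#'
#' Statistics following (under the null) a chi-square distribution with
#' `df` degrees of freedom are mapped through
#' \eqn{\Phi^{-1}(F_{\chi^2_\nu}(w))} to the z-scale, where the mixture
#' model operates.  The transform is strictly increasing; upper-tail
#' log-probabilities are used so that very large statistics stay finite.
#'
#' @param stats non-negative numeric statistics.
#' @param df degrees of freedom, a positive integer.
#' @return a [zscores] object.
#' @export
#' @examples
#' transform_to_z(c(0.45494, 3.8415), df = 1)  # about (0, 1.645)
transform_to_z <- function(stats, df) {
  zscores(chisq_to_z(stats, df))
}

#' @noRd
chisq_to_z <- function(stats, df) {
  stats <- as.numeric(stats)
  if (any(!is.finite(stats)) || any(stats < 0))
    stop("chi-square statistics must be finite and non-negative")
  if (length(df) != 1L || !is.finite(df) || df < 1)
    stop("df must be a single integer >= 1")
  lp <- stats::pchisq(stats, df = df, lower.tail = FALSE, log.p = TRUE)
  # guard against qnorm(-Inf upper-tail) = +Inf for astronomically
  # large statistics: clamp the log upper-tail away from -Inf
  lp <- pmax(lp, log(.Machine$double.xmin))
  stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
}

#' Genomic inflation factor of chi-square statistics
#'
#' \deqn{\lambda_{\chi^2_1} = \mathrm{median}(w_1, \ldots, w_p) / 0.456,}
#' the classical genomic-control estimator: the median of the observed
#' one-degree-of-freedom chi-square statistics over the theoretical null
#' median.  The printed constant 0.456 is used as is.
#'
#' @param w non-negative numeric statistics.
#' @return the inflation factor (positive scalar).
#' @export
genomic_inflation_chisq <- function(w) {
  w <- as.numeric(w)
  if (length(w) == 0L) stop("cannot compute an inflation factor on empty input")
  if (any(!is.finite(w)) || any(w < 0))
    stop("chi-square statistics must be finite and non-negative")
  stats::median(w) / 0.456
}

#' Genomic inflation factor on the z-scale
#'
#' For z-statistics from linear models the squared statistics play the
#' chi-square role, and the correction divides by the standard
#' deviation, not the variance: this returns
#' \eqn{\sqrt{\mathrm{median}(z^2)/0.456}}.
#'
#' @param z numeric vector or [zscores] object.
#' @return the z-scale inflation factor (positive scalar).
#' @export
genomic_inflation_z <- function(z) {
  sqrt(genomic_inflation_chisq(as.numeric(z)^2))
}

#' Corrected statistics container
#' @noRd
corrected_statistics <- function(corrected_z, corrected_beta = NULL,
                                 corrected_se = NULL, method,
                                 feature_ids = NULL) {
  p_value <- 2 * stats::pnorm(-abs(corrected_z))
  out <- list(corrected_z = as.numeric(corrected_z), p_value = p_value,
              corrected_beta = corrected_beta, corrected_se = corrected_se,
              method = method, feature_ids = feature_ids)
  class(out) <- "corrected_statistics"
  out
}

#' @export
print.corrected_statistics <- function(x, ...) {
  cat(sprintf("Corrected statistics (%s) for %d features\n",
              x$method, length(x$corrected_z)))
  cat(sprintf("  min p = %.3g, features with p < 0.05: %d\n",
              min(x$p_value), sum(x$p_value < 0.05)))
  invisible(x)
}

#' @export
as.data.frame.corrected_statistics <- function(x, ...) {
  d <- data.frame(corrected_z = x$corrected_z, p_value = x$p_value)
  if (!is.null(x$corrected_beta)) {
    d$corrected_beta <- x$corrected_beta
    d$corrected_se <- x$corrected_se
  }
  if (!is.null(x$feature_ids)) d <- cbind(feature_id = x$feature_ids, d)
  d
}

#' Genomic control on z-statistics
#'
#' Divides the statistics by the z-scale genomic inflation factor and
#' recomputes two-sided p-values from the standard normal.  Note that
#' the genomic inflation factor overestimates the true null spread
#' whenever a non-negligible fraction of features is truly associated,
#' making this correction conservative.
#'
#' @param z numeric vector or [zscores] object.
#' @return a `corrected_statistics` object.
#' @export
genomic_control_correct <- function(z) {
  zv <- as.numeric(z)
  lambda <- genomic_inflation_z(zv)
  corrected_statistics(zv / lambda, method = "gc",
                       feature_ids = attr(z, "feature_ids"))
}

#' Correct statistics with an estimated empirical null
#'
#' Standardises the statistics against the empirical null:
#' `corrected_z = (z - bias) / inflation`, with two-sided p-values from
#' the standard normal.  When effect sizes and standard errors are
#' supplied, they are corrected consistently so that the Wald ratio of
#' the corrected effect size equals the corrected z:
#' `corrected_beta = beta - bias * se`, `corrected_se = inflation * se`.
#'
#' @param z numeric vector or [zscores] object.
#' @param null an [empirical_null] (or an `empnull_fit`, whose `null` is
#'   used).
#' @param betas,ses optional effect sizes and standard errors, both
#'   present or both absent.
#' @return a `corrected_statistics` object.
#' @export
empirical_null_correct <- function(z, null, betas = NULL, ses = NULL) {
  if (inherits(null, "empnull_fit")) null <- null$null
  if (!inherits(null, "empirical_null"))
    null <- empirical_null(null[[1]], null[[2]])
  zv <- as.numeric(z)
  if (is.null(betas) != is.null(ses))
    stop("betas and ses must be both present or both absent")
  cz <- (zv - null$bias) / null$inflation
  cb <- cs <- NULL
  if (!is.null(betas)) {
    if (length(betas) != length(zv) || length(ses) != length(zv))
      stop("betas and ses must align with z")
    if (any(ses <= 0)) stop("standard errors must be strictly positive")
    cb <- betas - null$bias * ses
    cs <- null$inflation * ses
  }
  corrected_statistics(cz, cb, cs, method = "empirical",
                       feature_ids = attr(z, "feature_ids"))
}
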