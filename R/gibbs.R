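#' Data-dependent starting values for the mixture fit
#'
#' Initialises the null component at the median and (normal-consistent)
#' median absolute deviation of the statistics; the alternative
#' components start at median +/- 3 (the prior centres) with the same
#' spread, and the proportions at (0.9, 0.05, 0.05).  The MAD is floored
#' at 1e-3 so that degenerate (constant) inputs still yield valid
#' parameters.
#'
#' @param z numeric vector or [zscores] object.
#' @param offset distance of the alternative starting means from the
#'   median.
#' @return a [mixture_parameters] object.
#' @export
starting_values <- function(z, offset = 3) {
  z <- as.numeric(z)
  med <- stats::median(z)
  spread <- stats::mad(z)  # scaled by 1.4826 for normal consistency
  if (spread < 1e-3) {
    warning("MAD of the statistics is (near) zero; flooring the ",
            "starting spread at 1e-3")
    spread <- 1e-3
  }
  mixture_parameters(proportions = c(0.9, 0.05, 0.05),
                     means = c(med, med - offset, med + offset),
                     sds = rep(spread, 3))
}

#' Posterior membership probabilities of each statistic
#'
#' For each statistic, the probability that it belongs to each mixture
#' component, proportional to \eqn{\epsilon_j \phi(x_i; \mu_j,
#' \sigma_j)}.  Computed in log space and normalised by
#' log-sum-exp so that extreme statistics do not underflow.
#'
#' @param z numeric vector of z-scores.
#' @param params a [mixture_parameters] object.
#' @return a `length(z)` x 3 matrix of probabilities; rows sum to 1.
#'   Rows where all three densities underflow are set to `NA` (see
#'   [sample_labels] for the fallback).
#' @export
membership_probabilities <- function(z, params) {
  z <- as.numeric(z)
  logd <- vapply(1:3, function(j) {
    log(params$proportions[j]) +
      stats::dnorm(z, params$means[j], params$sds[j], log = TRUE)
  }, numeric(length(z)))
  logd <- matrix(logd, ncol = 3)
  mx <- apply(logd, 1L, max)
  p <- exp(logd - mx)
  p <- p / rowSums(p)
  p[!is.finite(mx), ] <- NA_real_
  colnames(p) <- c("null", "neg", "pos")
  p
}

#' Sample component labels given mixture parameters
#'
#' Draws one categorical label in \{1, 2, 3\} per statistic from its
#' posterior membership probabilities.  If all three component
#' densities underflow for a statistic, it is assigned to the component
#' with the nearest mean and a warning is emitted.
#'
#' @inheritParams membership_probabilities
#' @return integer vector of labels.
#' @export
sample_labels <- function(z, params) {
  z <- as.numeric(z)
  p <- length(z)
  # unnormalised, max-shifted densities: identical arithmetic to the
  # compiled sampler so that seeded runs agree bit-for-bit
  logd <- vapply(1:3, function(j) {
    log(params$proportions[j]) - log(params$sds[j]) -
      0.5 * ((z - params$means[j]) / params$sds[j])^2
  }, numeric(p))
  logd <- matrix(logd, ncol = 3)
  mx <- pmax(logd[, 1], logd[, 2], logd[, 3])
  dens <- exp(logd - mx)
  bad <- !is.finite(mx)
  labels <- integer(p)
  # no RNG is consumed for underflow rows (they are assigned
  # deterministically), mirroring the compiled sampler
  u <- stats::runif(sum(!bad)) * rowSums(dens[!bad, , drop = FALSE])
  labels[!bad] <- 1L + (u >= dens[!bad, 1]) +
    (u >= dens[!bad, 1] + dens[!bad, 2])
  if (any(bad)) {
    warning(sum(bad), " statistic(s) underflowed all components; ",
            "assigned to the nearest component mean")
    d <- abs(outer(z[bad], params$means, "-"))
    labels[bad] <- max.col(-d, ties.method = "first")
  }
  labels
}

#' One draw of the mixture parameters from their conditional posteriors
#'
#' Given component labels, draws the mixture proportions from
#' Dirichlet(\eqn{\gamma_j + n_j}), each component mean from its
#' conjugate normal conditional (prior \eqn{N(\lambda_j,
#' \sigma_j^2/\tau_j)}, using the current variance), and each component
#' precision from its conjugate gamma conditional (using the new mean).
#' Components with no members fall back to their prior.
#'
#' @param labels integer labels in \{1, 2, 3\}, as from [sample_labels].
#' @param z numeric vector of z-scores, aligned with `labels`.
#' @param hyper a [hyper_priors] object.
#' @param params current [mixture_parameters] (the component variances
#'   enter the conditional for the means).
#' @return a new [mixture_parameters] draw.
#' @export
sample_parameters <- function(labels, z, hyper, params) {
  z <- as.numeric(z)
  n <- vapply(1:3, function(j) sum(labels == j), numeric(1))
  s <- vapply(1:3, function(j) sum(z[labels == j]), numeric(1))
  ss <- vapply(1:3, function(j) sum(z[labels == j]^2), numeric(1))
  g <- stats::rgamma(3, shape = hyper$dirichlet + n, rate = 1)
  eps <- g / sum(g)
  denom <- hyper$prior_precisions + n
  mu <- stats::rnorm(3,
                     mean = (hyper$prior_precisions * hyper$prior_means + s) / denom,
                     sd = params$sds / sqrt(denom))
  SS <- pmax(ifelse(n > 0, ss - s^2 / pmax(n, 1), 0), 0)
  rate <- hyper$ig_rate +
    0.5 * hyper$prior_precisions * (mu - hyper$prior_means)^2 + 0.5 * SS
  prec <- stats::rgamma(3, shape = hyper$ig_shape + 0.5 * (n + 1), rate = rate)
  mixture_parameters(eps, mu, 1 / sqrt(prec))
}

#' Collapse statistics onto equally spaced bin centres
#'
#' Maps each statistic to the nearest of `n_bins` equally spaced
#' centres spanning `[min(z), max(z)]` and returns the centres with
#' their occupation counts.  Fitting on the binned representation
#' (weighted multinomial label sampling) is an approximation that
#' becomes exact when every value already lies on a bin centre.
#'
#' @param z numeric vector of z-scores.
#' @param n_bins number of bins (at least 2).
#' @return list with `centers` (numeric) and `weights` (integer counts
#'   summing to `length(z)`).
#' @export
bin_statistics <- function(z, n_bins = 1000L) {
  z <- as.numeric(z)
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stop("n_bins must be at least 2")
  lo <- min(z); hi <- max(z)
  if (hi == lo)
    return(list(centers = lo, weights = length(z)))
  width <- (hi - lo) / (n_bins - 1L)
  idx <- as.integer(round((z - lo) / width)) + 1L
  idx[idx > n_bins] <- n_bins
  weights <- tabulate(idx, nbins = n_bins)
  list(centers = lo + (seq_len(n_bins) - 1L) * width, weights = weights)
}

#' Fit the empirical null by Gibbs sampling of a three-component mixture
#'
#' Fits \eqn{f(x) = \sum_j \epsilon_j \phi(x; \mu_j, \sigma_j)} to a set
#' of z-scores, alternating label draws and conjugate parameter draws
#' for `n_burnin + n_keep` iterations, and summarises every parameter by
#' the arithmetic mean of the retained draws.  Component 1 (prior
#' centred at 0) is the null: its posterior-mean mean and sd are
#' returned as the bias and inflation of the statistics.
#'
#' @param z numeric vector or [zscores] object of test statistics.
#' @param hyper a [hyper_priors] object.
#' @param config a [gibbs_config] object; set `config$seed` for a
#'   reproducible fit.
#' @return an object of class `empnull_fit` with elements
#'   `null` ([empirical_null]), `params` (posterior-mean
#'   [mixture_parameters]), `trace` (data frame of retained draws),
#'   `z`, `hyper`, `config`.
#' @seealso [empirical_null_correct()] to apply the fitted null.
#' @export
#' @examples
#' z <- c(rnorm(900), rnorm(100, 4))
#' fit <- gibbs_fit(z, config = gibbs_config(n_burnin = 200, n_keep = 200,
#'                                           seed = 1))
#' fit$null
gibbs_fit <- function(z, hyper = hyper_priors(), config = gibbs_config()) {
  z <- as_zscores(z)
  stopifnot(inherits(hyper, "hyper_priors"), inherits(config, "gibbs_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  start <- starting_values(as.numeric(z))
  if (config$binned) {
    b <- bin_statistics(as.numeric(z), config$n_bins)
    keep <- b$weights > 0L
    values <- b$centers[keep]
    weights <- as.integer(b$weights[keep])
  } else {
    values <- sort(as.numeric(z))  # canonical order: fits are
    weights <- rep(1L, length(values))  # permutation-invariant
  }
  res <- gibbs_core(values, weights,
                    start$proportions, start$means, start$sds,
                    hyper$prior_means, hyper$prior_precisions,
                    hyper$ig_shape, hyper$ig_rate, hyper$dirichlet,
                    config$n_burnin, config$n_keep)
  if (res$n_underflow > 0)
    warning(res$n_underflow, " label draw(s) hit the density-underflow ",
            "fallback (nearest component mean)")
  trace <- as.data.frame(res$trace)
  names(trace) <- c("eps1", "eps2", "eps3", "mu1", "mu2", "mu3",
                    "sd1", "sd2", "sd3")
  trace$iteration <- config$n_burnin + seq_len(config$n_keep)
  pm <- colMeans(trace[, 1:9])
  params <- mixture_parameters(pm[1:3] / sum(pm[1:3]), pm[4:6], pm[7:9])
  structure(list(null = empirical_null(pm[["mu1"]], pm[["sd1"]]),
                 params = params,
                 trace = trace,
                 z = as.numeric(z),
                 n_features = length(z),
                 hyper = hyper,
                 config = config),
            class = "empnull_fit")
}

#' @export
print.empnull_fit <- function(x, ...) {
  cat(sprintf("Empirical-null mixture fit on %d statistics (%d burn-in + %d kept)\n",
              x$n_features, x$config$n_burnin, x$config$n_keep))
  cat(sprintf("  bias      = %8.4f\n", x$null$bias))
  cat(sprintf("  inflation = %8.4f\n", x$null$inflation))
  cat(sprintf("  proportions (null, neg, pos) = %.3f, %.3f, %.3f\n",
              x$params$proportions[1], x$params$proportions[2],
              x$params$proportions[3]))
  invisible(x)
}
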