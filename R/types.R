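#' Construct a validated set of z-scores
#'
#' A `zscores` object is a plain numeric vector of per-feature test
#' statistics on the z-scale, optionally carrying feature identifiers.
#' All downstream estimation functions accept either a bare numeric
#' vector or a `zscores` object.
#'
#' @param values numeric vector of z-scores, one per feature; must be
#'   finite and of length at least 2.
#' @param feature_ids optional character vector of feature labels,
#'   recycled never; must match `length(values)` when given.
#' @return a numeric vector of class `zscores` with an optional
#'   `feature_ids` attribute.
#' @export
#' @examples
#' z <- zscores(c(-1.2, 0.3, 2.5), feature_ids = c("cg1", "cg2", "cg3"))
zscores <- function(values, feature_ids = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("at least 2 z-scores are required, got ", length(values))
  if (!all(is.finite(values)))
    stop("z-scores must all be finite; found ",
         sum(!is.finite(values)), " non-finite value(s)")
  if (!is.null(feature_ids)) {
    feature_ids <- as.character(feature_ids)
    if (length(feature_ids) != length(values))
      stop("feature_ids must have the same length as values")
    attr(values, "feature_ids") <- feature_ids
  }
  class(values) <- c("zscores", "numeric")
  values
}

#' @rdname zscores
#' @param x object to coerce / test.
#' @export
as_zscores <- function(x) {
  if (inherits(x, "zscores")) return(x)
  zscores(x, feature_ids = attr(x, "feature_ids"))
}

#' Three-component normal mixture parameters
#'
#' Container for the parameters of the mixture
#' \deqn{f(x) = \sum_{j=1}^{3} \epsilon_j \phi(x; \mu_j, \sigma_j),}
#' where component 1 is, by construction (its prior is centred at 0),
#' the null component whose mean and standard deviation are the
#' test-statistic bias and inflation.  Components 2 and 3 capture the
#' negatively and positively associated features (priors centred at -3
#' and +3).
#'
#' @param proportions numeric(3), mixture weights in `[0, 1]` summing
#'   to 1 (within 1e-12).
#' @param means numeric(3) component means.
#' @param sds numeric(3) strictly positive component standard deviations.
#' @return a list of class `mixture_parameters`.
#' @export
mixture_parameters <- function(proportions, means, sds) {
  proportions <- as.numeric(proportions)
  means <- as.numeric(means)
  sds <- as.numeric(sds)
  if (length(proportions) != 3L || length(means) != 3L || length(sds) != 3L)
    stop("proportions, means and sds must each have length 3")
  if (any(!is.finite(c(proportions, means, sds))))
    stop("mixture parameters must be finite")
  if (any(proportions < 0) || any(proportions > 1))
    stop("proportions must lie in [0, 1]")
  if (abs(sum(proportions) - 1) > 1e-12)
    stop("proportions must sum to 1 (within 1e-12), got ",
         format(sum(proportions), digits = 16))
  if (any(sds <= 0))
    stop("all component sds must be strictly positive")
  structure(list(proportions = proportions, means = means, sds = sds),
            class = "mixture_parameters")
}

#' @export
print.mixture_parameters <- function(x, ...) {
  cat("Three-component normal mixture\n")
  m <- rbind(proportion = x$proportions, mean = x$means, sd = x$sds)
  colnames(m) <- c("null", "neg", "pos")
  print(round(m, 4))
  invisible(x)
}

#' Hyper-priors for the Gibbs sampler
#'
#' Conjugate prior hyper-parameters for the three-component mixture.
#' Component means have normal priors \eqn{\mu_j \sim N(\lambda_j,
#' \sigma_j^2/\tau_j)} with informative centres (0, -3, +3) that pin
#' component 1 to the null and suppress label switching; \eqn{\tau_j}
#' acts as a prior pseudo-count.  Component variances have inverse-gamma
#' priors IG(`ig_shape`, `ig_rate`); the defaults (1.28, 0.36) follow
#' the weakly informative choice of Raftery.  Mixture proportions have a
#' Dirichlet(90, 5, 5) prior: the method's core assumption is that the
#' null component is an unknown *majority* of the features, and the
#' informative Dirichlet (total prior weight 100, a few percent of a
#' typical feature set) keeps the null component from collapsing when
#' the statistics are severely inflated.  A flat Dirichlet(1, 1, 1) can
#' be requested but degenerates under strong inflation; see the
#' vignette.
#'
#' @param prior_means numeric(3) prior centres \eqn{\lambda_j}.
#' @param prior_precisions numeric(3) positive pseudo-counts \eqn{\tau_j}.
#' @param ig_shape,ig_rate positive scalars of the inverse-gamma prior
#'   on component variances.
#' @param dirichlet numeric(3) positive Dirichlet parameters
#'   \eqn{\gamma_j}.
#' @return a list of class `hyper_priors`.
#' @export
hyper_priors <- function(prior_means = c(0, -3, 3),
                         prior_precisions = c(100, 100, 100),
                         ig_shape = 1.28,
                         ig_rate = 0.36,
                         dirichlet = c(90, 5, 5)) {
  stopifnot(length(prior_means) == 3L, length(prior_precisions) == 3L,
            length(dirichlet) == 3L)
  if (any(prior_precisions <= 0) || ig_shape <= 0 || ig_rate <= 0 ||
      any(dirichlet <= 0))
    stop("prior precisions, ig_shape, ig_rate and dirichlet parameters ",
         "must all be strictly positive")
  structure(list(prior_means = as.numeric(prior_means),
                 prior_precisions = as.numeric(prior_precisions),
                 ig_shape = as.numeric(ig_shape),
                 ig_rate = as.numeric(ig_rate),
                 dirichlet = as.numeric(dirichlet)),
            class = "hyper_priors")
}

#' Run-length and sampling configuration for the Gibbs sampler
#'
#' Defaults follow the reference run length: 3000 burn-in iterations
#' followed by 2000 retained samples (5000 total).  When `binned = TRUE`
#' the statistics are collapsed onto `n_bins` equally spaced bin centres
#' (weighted multinomial sampling), trading a little resolution for
#' speed on very large feature sets.
#'
#' @param n_burnin,n_keep positive integers; iterations discarded /
#'   retained.
#' @param seed optional integer seed; when given, the fit is fully
#'   reproducible.
#' @param binned logical, fit on binned statistics.
#' @param n_bins number of bins when `binned`.
#' @return a list of class `gibbs_config`.
#' @export
gibbs_config <- function(n_burnin = 3000L, n_keep = 2000L, seed = NULL,
                         binned = FALSE, n_bins = 1000L) {
  n_burnin <- as.integer(n_burnin)
  n_keep <- as.integer(n_keep)
  n_bins <- as.integer(n_bins)
  if (is.na(n_burnin) || n_burnin < 1L) stop("n_burnin must be a positive integer")
  if (is.na(n_keep) || n_keep < 1L) stop("n_keep must be a positive integer")
  if (is.na(n_bins) || n_bins < 2L) stop("n_bins must be at least 2")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(n_burnin = n_burnin, n_keep = n_keep, seed = seed,
                 binned = isTRUE(binned), n_bins = n_bins),
            class = "gibbs_config")
}

#' Empirical null distribution
#'
#' The normal distribution actually followed by the unassociated
#' features' statistics: its mean is the test-statistic bias, its
#' standard deviation the inflation.
#'
#' @param bias real; mean of the null component.
#' @param inflation strictly positive real; sd of the null component.
#' @return a list of class `empirical_null`.
#' @export
empirical_null <- function(bias, inflation) {
  bias <- as.numeric(bias)
  inflation <- as.numeric(inflation)
  if (length(bias) != 1L || length(inflation) != 1L ||
      !is.finite(bias) || !is.finite(inflation))
    stop("bias and inflation must be finite scalars")
  if (inflation <= 0) stop("inflation must be strictly positive")
  structure(list(bias = bias, inflation = inflation),
            class = "empirical_null")
}

#' @export
print.empirical_null <- function(x, ...) {
  cat(sprintf("Empirical null: bias = %.4f, inflation = %.4f\n",
              x$bias, x$inflation))
  invisible(x)
}
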