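#' Per-feature linear-model association statistics
#'
#' Ordinary least squares of every feature (column of `Y`) on an
#' intercept, the covariate of interest `x`, and optional additional
#' covariates `C`.  Returns the coefficient of `x`, its standard error,
#' and the t-statistic treated as a z-score -- the large-sample
#' convention appropriate for n in the hundreds; it is not valid for
#' small n.  Standard errors of numerically perfect fits are floored at
#' `2^-1022` so that the returned statistics stay finite (and enormous).
#'
#' @param Y numeric matrix, samples by features.
#' @param x numeric covariate of interest, length `nrow(Y)`.
#' @param C optional numeric matrix of additional covariates.
#' @return a list of class `assoc_result` with `z` ([zscores]), `beta`,
#'   `se`, and residual degrees of freedom `df`.
#' @export
per_feature_lm <- function(Y, x, C = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (length(x) != n) stop("x must have one value per row of Y")
  design <- cbind(`(intercept)` = 1, x = x)
  if (!is.null(C)) {
    C <- as.matrix(C)
    if (nrow(C) != n) stop("C must have one row per row of Y")
    if (is.null(colnames(C))) colnames(C) <- paste0("C", seq_len(ncol(C)))
    design <- cbind(design, C)
  }
  k <- ncol(design)
  if (n <= k) stop("need more samples (", n, ") than covariates (", k, ")")
  qrd <- qr(design)
  if (qrd$rank < k) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):k]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  coefs <- qr.coef(qrd, Y)
  resid <- Y - design %*% coefs
  df <- n - k
  sigma2 <- colSums(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qrd))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  se <- pmax(se, .Machine$double.xmin)
  beta <- coefs[2, ]
  structure(list(z = zscores(beta / se), beta = as.numeric(beta),
                 se = as.numeric(se), df = df),
            class = "assoc_result")
}

#' False positive rate and power at a significance threshold
#'
#' @param p_values numeric p-values per feature.
#' @param truth character/factor per feature, `"null"` or `"alt"`; must
#'   contain at least one of each.
#' @param alpha significance level.
#' @return named numeric `c(fpr = , power = )`: the fraction of null
#'   features with `p < alpha` and the fraction of alternative features
#'   with `p < alpha`.
#' @export
evaluate_fpr_power <- function(p_values, truth, alpha = 0.05) {
  truth <- as.character(truth)
  if (length(p_values) != length(truth))
    stop("p_values and truth must be aligned")
  if (!all(truth %in% c("null", "alt")))
    stop("truth labels must be 'null' or 'alt'")
  is_null <- truth == "null"
  if (!any(is_null) || all(is_null))
    stop("truth must contain at least one null and one alternative feature")
  c(fpr = mean(p_values[is_null] < alpha),
    power = mean(p_values[!is_null] < alpha))
}

# p-values for one replicate's statistics under each correction method
apply_correction <- function(z, method, config) {
  switch(method,
         none = 2 * stats::pnorm(-abs(as.numeric(z))),
         gc = genomic_control_correct(z)$p_value,
         empirical = {
           fit <- gibbs_fit(z, config = config)
           empirical_null_correct(z, fit$null)$p_value
         },
         stop("unknown correction method: ", method))
}

#' Replicated FPR/power benchmark over the simulation scenarios
#'
#' Runs `n_reps` seeded replicates of a simulation scenario, applies
#' each requested correction method, and summarises false positive rate
#' and power at level `alpha` across replicates.
#'
#' Scenarios: `"table3-uncorrelated"` (2000 independent z, 90% null,
#' alternatives centred at +/-3), `"table3-correlated"` (same with
#' block-correlated nulls: 10 blocks, within-block correlation 0.5),
#' `"table2"` (confounded data matrix, per-feature regression on the
#' covariate of interest only -- except for method `"oracle"`, which
#' additionally includes the true simulated confounders and applies no
#' statistic correction), and `"fig2"` (no FPR/power: reports the mean
#' genomic and Bayesian inflation estimates at alternative fractions
#' 5%, 10%, and 20% with no true inflation).
#'
#' @param scenario one of `"table3-uncorrelated"`, `"table3-correlated"`,
#'   `"table2"`, `"fig2"`.
#' @param methods subset of `"none"`, `"gc"`, `"empirical"`, plus
#'   `"oracle"` for `"table2"`.
#' @param n_reps number of replicates.
#' @param base_seed integer; replicate `i` uses seed `base_seed + i - 1`.
#' @param alpha significance level.
#' @param config [gibbs_config] used by the `"empirical"` method (leave
#'   the seed `NULL`: the replicate seed already fixes the stream).
#' @param prop_alt alternative fractions used by scenario `"fig2"`.
#' @return a list of class `benchmark_result` with `summary` (per
#'   method: mean and sd of FPR and power across replicates) and
#'   `replicates` (long format).
#' @export
run_benchmark <- function(scenario = c("table3-uncorrelated",
                                       "table3-correlated",
                                       "table2", "fig2"),
                          methods = c("none", "gc", "empirical"),
                          n_reps = 100, base_seed = 1, alpha = 0.05,
                          config = gibbs_config(),
                          prop_alt = c(0.05, 0.1, 0.2)) {
  scenario <- match.arg(scenario)
  if (scenario == "fig2")
    return(run_inflation_study(prop_alt, n_reps, base_seed, config))
  if ("oracle" %in% methods && scenario != "table2")
    stop("the oracle method is only defined for the 'table2' scenario")
  rows <- vector("list", n_reps * length(methods))
  ri <- 0L
  for (i in seq_len(n_reps)) {
    seed_i <- base_seed + i - 1L
    if (scenario == "table2") {
      sim <- simulate_confounded(seed = seed_i)
      naive <- per_feature_lm(sim$Y, sim$X)
      z <- naive$z
      oracle_p <- if ("oracle" %in% methods) {
        2 * stats::pnorm(-abs(as.numeric(per_feature_lm(sim$Y, sim$X, sim$Z)$z)))
      }
    } else {
      sim <- if (scenario == "table3-correlated")
        simulate_correlated_z(seed = seed_i)
      else simulate_mixture_z(seed = seed_i)
      z <- sim$z
    }
    for (m in methods) {
      p <- if (m == "oracle") oracle_p else apply_correction(z, m, config)
      fp <- evaluate_fpr_power(p, sim$truth, alpha)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(replicate = i, seed = seed_i, method = m,
                               fpr = fp[["fpr"]], power = fp[["power"]])
    }
  }
  replicates <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(replicates, replicates$method),
                                   function(d) data.frame(
    method = d$method[1],
    fpr_mean = mean(d$fpr), fpr_sd = stats::sd(d$fpr),
    power_mean = mean(d$power), power_sd = stats::sd(d$power))))
  summary <- summary[match(intersect(methods, summary$method),
                           summary$method), ]
  rownames(summary) <- NULL
  structure(list(scenario = scenario, alpha = alpha, n_reps = n_reps,
                 base_seed = base_seed, summary = summary,
                 replicates = replicates),
            class = "benchmark_result")
}

# inflation estimates vs. fraction of true associations (no true
# inflation): the genomic inflation factor grows with the fraction,
# the mixture-based estimate should not
run_inflation_study <- function(prop_alt, n_reps, base_seed, config) {
  rows <- list()
  for (f in prop_alt) {
    for (i in seq_len(n_reps)) {
      seed_i <- base_seed + i - 1L
      sim <- simulate_mixture_z(n = 2000, prop_null = 1 - f,
                                alt_mean_center = 4, seed = seed_i)
      fit <- gibbs_fit(sim$z, config = config)
      rows[[length(rows) + 1L]] <- data.frame(
        prop_alt = f, replicate = i, seed = seed_i,
        gc = genomic_inflation_z(sim$z),
        empirical = fit$null$inflation)
    }
  }
  replicates <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(replicates, replicates$prop_alt),
                                   function(d) data.frame(
    prop_alt = d$prop_alt[1],
    gc_mean = mean(d$gc), gc_sd = stats::sd(d$gc),
    empirical_mean = mean(d$empirical),
    empirical_sd = stats::sd(d$empirical))))
  rownames(summary) <- NULL
  structure(list(scenario = "fig2", n_reps = n_reps, base_seed = base_seed,
                 summary = summary, replicates = replicates),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Benchmark '%s': %d replicates (base seed %d)\n",
              x$scenario, x$n_reps, x$base_seed))
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
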