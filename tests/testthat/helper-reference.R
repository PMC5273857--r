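# Pure-R reference Gibbs loop, composed from the exported single-step
# operations.  Used as an independent route against the compiled
# sampler: with the same seed both must produce bit-identical traces.
reference_gibbs <- function(z, hyper = hyper_priors(),
                            n_burnin = 50L, n_keep = 50L, seed = 1L) {
  set.seed(seed)
  params <- starting_values(z)
  zs <- sort(as.numeric(z))
  trace <- matrix(NA_real_, n_keep, 9)
  for (t in seq_len(n_burnin + n_keep)) {
    labels <- sample_labels(zs, params)
    params <- sample_parameters(labels, zs, hyper, params)
    if (t > n_burnin)
      trace[t - n_burnin, ] <- c(params$proportions, params$means,
                                 params$sds)
  }
  colnames(trace) <- c("eps1", "eps2", "eps3", "mu1", "mu2", "mu3",
                       "sd1", "sd2", "sd3")
  trace
}

# two-sided standard-normal p-values
pz <- function(z) 2 * stats::pnorm(-abs(as.numeric(z)))
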