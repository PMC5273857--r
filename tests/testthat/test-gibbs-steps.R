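test_that("starting values track the median and scaled MAD", {
  set.seed(11)
  s <- starting_values(rnorm(1e5))
  expect_lt(abs(s$means[1]), 0.02)
  expect_gt(s$sds[1], 0.97)
  expect_lt(s$sds[1], 1.03)
  s2 <- starting_values(rnorm(1e5, 0.5, 2))
  expect_equal(s2$means[1], 0.5, tolerance = 0.05)
  expect_equal(s2$sds[1], 2.0, tolerance = 0.05 * 2)
  expect_equal(s2$means[2:3], s2$means[1] + c(-3, 3))
  expect_equal(s$proportions, c(0.9, 0.05, 0.05))
})

test_that("constant input floors the MAD with a warning", {
  expect_warning(s <- starting_values(rep(3, 10)), "floor")
  expect_equal(s$means[1], 3)
  expect_equal(s$sds[1], 1e-3)
})

test_that("membership probabilities at x = 0 match the closed form", {
  # normalize phi(0;0,1) : phi(0;-3,1) : phi(0;3,1) = 1 : e^-4.5 : e^-4.5
  params <- mixture_parameters(rep(1 / 3, 3), c(0, -3, 3), c(1, 1, 1))
  p <- membership_probabilities(0, params)[1, ]
  e45 <- exp(-4.5)
  expect_equal(unname(p), c(1, e45, e45) / (1 + 2 * e45), tolerance = 1e-10)
  expect_equal(unname(round(p, 4)), c(0.9783, 0.0109, 0.0109))
})

test_that("degenerate proportions force a single label", {
  params <- mixture_parameters(c(1, 0, 0), c(0, -3, 3), c(1, 1, 1))
  set.seed(1)
  expect_true(all(sample_labels(rnorm(100), params) == 1L))
})

test_that("label frequencies converge to the membership probabilities", {
  params <- mixture_parameters(rep(1 / 3, 3), c(0, -3, 3), c(1, 1, 1))
  set.seed(42)
  labs <- sample_labels(rep(0, 1e5), params)
  freq <- tabulate(labs, 3) / 1e5
  expect_equal(freq, unname(membership_probabilities(0, params)[1, ]),
               tolerance = 0.005)
})

test_that("underflow falls back to the nearest component mean", {
  # z so extreme that (z - mu)^2 / sd^2 overflows: all three log
  # densities are -Inf and the labels are assigned deterministically
  params <- mixture_parameters(rep(1 / 3, 3), c(0, -400, 400), c(1, 1, 1))
  set.seed(1)
  expect_warning(labs <- sample_labels(c(-1e200, 0.1, 1e200), params),
                 "underflow")
  expect_identical(labs[1], 1L)  # distances tie at 1e200; first wins
  expect_identical(labs[3], 1L)
  expect_true(labs[2] %in% 1:3)
})

test_that("parameter draws satisfy the conjugate identities", {
  hyper <- hyper_priors()
  base <- mixture_parameters(c(0.9, 0.05, 0.05), c(0, -3, 3), c(1, 1, 1))
  # prior-dominated limit: tau -> infinity pins mu at lambda
  hp <- hyper_priors(prior_precisions = rep(1e12, 3))
  set.seed(5)
  mus <- replicate(1e4, sample_parameters(c(1L, 2L, 3L), c(5, -5, 5),
                                          hp, base)$means[1])
  expect_lt(sd(mus), 1e-4)
  expect_equal(mean(mus), 0, tolerance = 1e-4)

  # data-dominated limit: posterior mean of mu_j ~ (tau*lambda + n*m)/(tau + n)
  set.seed(6)
  x <- rnorm(1e5, 2, 1)
  m <- mean(x)
  draws <- replicate(200, sample_parameters(rep(1L, 1e5), x, hyper, base)$means[1])
  expect_equal(mean(draws), (100 * 0 + 1e5 * m) / (100 + 1e5), tolerance = 0.005)

  # Dirichlet mean identity: E eps_j = (gamma_j + n_j) / sum(gamma + n)
  set.seed(7)
  labels <- rep(c(1L, 2L, 3L), c(60, 25, 15))
  x <- rnorm(100)
  eps <- replicate(4000, sample_parameters(labels, x, hyper, base)$proportions)
  expected <- (hyper$dirichlet + c(60, 25, 15)) /
    sum(hyper$dirichlet + c(60, 25, 15))
  expect_equal(rowMeans(eps), expected, tolerance = 0.01)
})

test_that("binning conserves counts and lossless binning is exact", {
  set.seed(8)
  z <- rnorm(5000)
  b <- bin_statistics(z, 100)
  expect_equal(sum(b$weights), 5000)
  expect_equal(length(b$centers), 100)

  # values already on a uniform grid: binned fit == raw fit, same seed
  zg <- rep(seq(-3, 3, length.out = 41), times = 5)
  cfg_raw <- gibbs_config(n_burnin = 50, n_keep = 50, seed = 99)
  cfg_bin <- gibbs_config(n_burnin = 50, n_keep = 50, seed = 99,
                          binned = TRUE, n_bins = 41)
  f1 <- gibbs_fit(zg, config = cfg_raw)
  f2 <- gibbs_fit(zg, config = cfg_bin)
  expect_identical(f1$trace[, 1:9], f2$trace[, 1:9])
})

test_that("1000-bin approximation is close to the raw fit", {
  # scaled down from the spec example (1e5 points, full run) to keep the
  # suite fast; the comparison is between two fits of the same data so
  # the 0.02 tolerance carries over
  set.seed(9)
  z <- rnorm(2e4)
  cfg <- function(binned) gibbs_config(n_burnin = 500, n_keep = 500,
                                       seed = 13, binned = binned)
  f_raw <- gibbs_fit(z, config = cfg(FALSE))
  f_bin <- gibbs_fit(z, config = cfg(TRUE))
  expect_lt(abs(f_raw$null$bias - f_bin$null$bias), 0.02)
  expect_lt(abs(f_raw$null$inflation - f_bin$null$inflation), 0.02)
})
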