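test_that("generators are reproducible and truth counts are exact", {
  a <- simulate_mixture_z(500, seed = 3)
  b <- simulate_mixture_z(500, seed = 3)
  expect_identical(as.numeric(a$z), as.numeric(b$z))
  expect_identical(a$truth, b$truth)
  expect_equal(sum(a$truth == "null"), 450)
  expect_equal(sum(simulate_mixture_z(2000, 0.9, seed = 1)$truth == "null"),
               1800)
  c1 <- simulate_confounded(n = 30, p = 100, seed = 4)
  c2 <- simulate_confounded(n = 30, p = 100, seed = 4)
  expect_identical(c1$Y, c2$Y)
})

test_that("all-null output carries exactly the configured bias and inflation", {
  sim <- simulate_mixture_z(2000, prop_null = 1, null_bias = 0.5,
                            null_inflation = 1.5, seed = 5)
  expect_true(all(sim$truth == "null"))
  expect_equal(genomic_inflation_z(as.numeric(sim$z) - 0.5), 1.5,
               tolerance = 0.08 / 1.5)
  expect_equal(mean(as.numeric(sim$z)), 0.5, tolerance = 0.1)
})

test_that("skew controls the sign of the alternative means", {
  # the drawn means scatter N(+/-3, 1) around the signed centres, so we
  # check their averages rather than exact sign counts
  sim <- simulate_mixture_z(1000, prop_null = 0.9, skew = 1, seed = 6)
  expect_lt(abs(mean(sim$mu[sim$truth == "alt"]) - 3), 0.5)
  sim2 <- simulate_mixture_z(1000, prop_null = 0.9, skew = 0.5, seed = 6)
  expect_lt(abs(mean(sim2$mu[sim2$truth == "alt"])), 0.5)
})

test_that("zero block correlation reproduces the independent generator exactly", {
  a <- simulate_mixture_z(800, seed = 7)
  b <- simulate_correlated_z(800, within_block_corr = 0, seed = 7)
  expect_identical(as.numeric(a$z), as.numeric(b$z))
})

test_that("block construction attains the configured correlation at unit variance", {
  # many small blocks so that the Monte-Carlo error of the block-factor
  # variance (the dominant noise term, ~sqrt(2/n_blocks)) resolves the
  # stated 0.01/0.02 bands
  n <- 1e5; bs <- 5
  sim <- simulate_correlated_z(n, prop_null = 1, n_blocks = n / bs,
                               within_block_corr = 0.5, seed = 8)
  z <- as.numeric(sim$z)
  expect_equal(var(z), 1, tolerance = 0.02)
  # average within-block covariance of distinct pairs estimates rho
  m <- matrix(z, nrow = bs)
  s1 <- colSums(m); s2 <- colSums(m^2)
  paircov <- sum(s1^2 - s2) / (bs * (bs - 1) * ncol(m))
  expect_equal(paircov, 0.5, tolerance = 0.01 / 0.5)
})

test_that("correlated nulls inflate the replicate-to-replicate FPR variance", {
  fpr <- function(gen) vapply(1:15, function(i) {
    sim <- gen(i)
    unname(evaluate_fpr_power(pz(sim$z), sim$truth)["fpr"])
  }, numeric(1))
  f_ind <- fpr(function(i) simulate_mixture_z(seed = i))
  f_cor <- fpr(function(i) simulate_correlated_z(seed = i))
  expect_gt(var(f_cor), var(f_ind))
})

test_that("genomic inflation grows with the fraction of true associations", {
  mean_lambda <- vapply(c(0.95, 0.90, 0.80), function(pn) {
    mean(vapply(1:10, function(i) {
      genomic_inflation_z(simulate_mixture_z(2000, pn, seed = 300 + i)$z)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_lambda) > 0))
  expect_true(all(mean_lambda > 1))
})

test_that("confounded generator has the documented shape and null behaviour", {
  sim <- simulate_confounded(seed = 9)
  expect_equal(dim(sim$Y), c(100, 2000))
  expect_equal(dim(sim$Z), c(100, 5))
  expect_equal(sum(sim$truth == "null"), 1800)
  # no confounding, no effects, no latent structure: naive z-statistics
  # are standard normal (with gamma_sd > 0 the latent factors inflate
  # the statistics even at confounding_strength 0, because their
  # in-sample correlation with X is not exactly zero)
  null_sim <- simulate_confounded(n = 100, p = 1000,
                                  confounding_strength = 0, effect_sd = 0,
                                  gamma_sd = 0, seed = 10)
  z <- as.numeric(per_feature_lm(null_sim$Y, null_sim$X)$z)
  expect_lt(abs(mean(z)), 0.1)
  expect_gt(sd(z), 0.9)
  expect_lt(sd(z), 1.1)
})

test_that("oracle adjustment restores nominal type-I error", {
  fpr <- vapply(1:10, function(i) {
    sim <- simulate_confounded(seed = 40 + i)
    res <- per_feature_lm(sim$Y, sim$X, sim$Z)
    unname(evaluate_fpr_power(pz(res$z), sim$truth)["fpr"])
  }, numeric(1))
  expect_lt(abs(mean(fpr) - 0.05), 0.02)
})
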