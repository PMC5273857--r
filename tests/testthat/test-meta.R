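make_study <- function(id, n, bias = 0, inflation = 1, seed = 1) {
  set.seed(seed)
  z <- rnorm(n, bias, inflation)
  study_summary(sprintf("f%04d", seq_len(n)), beta = z, se = rep(1, n),
                study_id = id)
}

test_that("inverse-variance pooling matches hand-computed values", {
  one <- study_summary(c("a", "b"), c(1, 2), c(0.5, 0.25), "s1")
  pooled1 <- fixed_effect_meta(list(one))
  expect_equal(pooled1$beta, one$beta)
  expect_equal(pooled1$se, one$se)

  s1 <- study_summary("f1", 1, 1, "A")
  s2 <- study_summary("f1", 1, 1, "B")
  expect_equal(fixed_effect_meta(list(s1, s2))$se, 1 / sqrt(2),
               tolerance = 1e-10)

  s2b <- study_summary("f1", 2, 0.5, "B")
  pooled <- fixed_effect_meta(list(s1, s2b))
  expect_equal(pooled$beta, 1.8)
  expect_equal(pooled$se, 0.44721, tolerance = 1e-5)
  expect_equal(pooled$z, 1.8 / sqrt(0.2), tolerance = 1e-10)
})

test_that("pooling is order-invariant and strictly gains precision", {
  studies <- lapply(1:3, function(k) make_study(paste0("s", k), 50, seed = k))
  a <- fixed_effect_meta(studies)
  b <- fixed_effect_meta(rev(studies))
  expect_equal(a, b)
  expect_true(all(a$se < min(vapply(studies, function(s) min(s$se),
                                    numeric(1)))))
})

test_that("invalid standard errors are reported with study and feature", {
  bad <- data.frame(feature_id = c("f1", "f2"), beta = c(1, 2), se = c(1, 0))
  expect_error(fixed_effect_meta(list(ok = make_study("ok", 2), bad = bad)),
               "bad.*f2")
})

test_that("join behaviour over non-shared features is defined", {
  s1 <- study_summary(c("a", "b"), c(1, 1), c(1, 1), "s1")
  s2 <- study_summary(c("b", "c"), c(2, 2), c(1, 1), "s2")
  inner <- fixed_effect_meta(list(s1, s2), join = "inner")
  expect_equal(inner$feature_id, "b")
  avail <- fixed_effect_meta(list(s1, s2), join = "available")
  expect_equal(avail$feature_id, c("a", "b", "c"))
  expect_equal(avail$n_studies, c(1L, 2L, 1L))
  expect_equal(avail$beta, c(1, 1.5, 2))
})

test_that("per-study correction removes simulated bias and inflation", {
  cfg <- gibbs_config(n_burnin = 600, n_keep = 600, seed = 5)
  studies <- list(make_study("A", 1500, bias = 0.3, inflation = 1.4, seed = 41),
                  make_study("B", 1500, bias = -0.2, inflation = 1.2, seed = 42))
  res <- empnull_meta(studies, config = cfg)
  expect_lt(max(abs(res$study_nulls$bias - c(0.3, -0.2))), 0.1)
  expect_lt(max(abs(res$study_nulls$inflation - c(1.4, 1.2))), 0.12)
  # residual null of corrected pooled statistics is near (0, 1)
  expect_lt(abs(res$pooled_null$bias), 0.06)
  expect_lt(abs(res$pooled_null$inflation - 1), 0.1)
  # scale-consistency: rescaling one study's (beta, se) leaves its
  # z-scores, hence its fitted null, unchanged
  studies2 <- studies
  studies2[[2]]$beta <- 10 * studies2[[2]]$beta
  studies2[[2]]$se <- 10 * studies2[[2]]$se
  res2 <- empnull_meta(studies2, config = cfg)
  expect_equal(res2$study_nulls, res$study_nulls)
})

test_that("with standard-normal studies the corrected meta-analysis is a near no-op", {
  cfg <- gibbs_config(n_burnin = 600, n_keep = 600, seed = 9)
  studies <- list(make_study("A", 1500, seed = 51), make_study("B", 1500, seed = 52))
  plain <- fixed_effect_meta(studies)
  corrected <- empnull_meta(studies, config = cfg)
  expect_lt(max(abs(plain$beta - corrected$pooled$beta)), 0.1)
  expect_gt(cor(plain$beta, corrected$pooled$beta), 0.99)
})
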