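test_that("welch_t reproduces the hand-computed two-sample example", {
  fx <- two_group_expr(c(4, 5, 6), c(1, 2, 3))
  res <- welch_t(fx$expr, fx$design)
  expect_equal(res$t, 3.674235, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 0.02131164, tolerance = 1e-6)
  expect_equal(res$log2_fc, 3)
  expect_false(res$degenerate)
})

test_that("welch_t agrees with stats::t.test gene by gene", {
  set.seed(8)
  sim <- simulate_expression(sim_config(25, 4, 6, deg_fraction = 0.2,
                                        seed = 8))
  res <- welch_t(sim$expr, sim$design)
  for (i in seq_len(25)) {
    tt <- t.test(sim$expr[i, 1:4], sim$expr[i, 5:10])
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$df[i], unname(tt$parameter), tolerance = 1e-10)
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("welch_t symmetry, degeneracy and label-swap behaviour", {
  fx <- two_group_expr(c(2, 3, 4), c(2, 3, 4))
  res <- welch_t(fx$expr, fx$design)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)

  # constant but different groups: flagged, p at the representable floor
  fx2 <- two_group_expr(c(5, 5, 5), c(1, 1, 1))
  res2 <- welch_t(fx2$expr, fx2$design)
  expect_true(res2$degenerate)
  expect_identical(res2$p_value, .Machine$double.xmin)

  # swapping group labels negates t, keeps p
  fx3 <- two_group_expr(c(4, 6, 9), c(1, 2, 3))
  swapped <- fx3$design
  swapped$group <- ifelse(swapped$group == "case", "control", "case")
  a <- welch_t(fx3$expr, fx3$design)
  b <- welch_t(fx3$expr, swapped)
  expect_equal(a$t, -b$t)
  expect_equal(a$p_value, b$p_value)

  # permuting samples within groups changes nothing
  perm <- fx3$expr[, c(2, 1, 3, 5, 4, 6), drop = FALSE]
  expect_equal(welch_t(perm, fx3$design)[, -1], a[, -1])
})

test_that("variance prior estimation recovers known hyperparameters", {
  # degenerate: equal variances => infinite prior df
  pr <- estimate_variance_prior(rep(0.3, 50), 8)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_sq, 0.3)

  # recovery from the generative model
  set.seed(17)
  s2 <- (0.05 * 4 / rchisq(2000, 4)) * rchisq(2000, 8) / 8
  fit <- estimate_variance_prior(s2, 8)
  expect_lt(abs(fit$d0 - 4) / 4, 0.3)
  expect_lt(abs(fit$s0_sq - 0.05) / 0.05, 0.2)

  # scale equivariance
  fit2 <- estimate_variance_prior(2 * s2, 8)
  expect_equal(fit2$s0_sq, 2 * fit$s0_sq, tolerance = 1e-8)
  expect_equal(fit2$d0, fit$d0, tolerance = 1e-6)
})

test_that("moderated t has the correct no- and full-moderation limits", {
  sim <- simulate_expression(sim_config(40, 4, 5, deg_fraction = 0.1,
                                        seed = 31))
  # d0 = 0: ordinary pooled-variance t
  none <- moderated_t(sim$expr, sim$design, d0 = 0, s0_sq = 1)
  k1 <- 4; k2 <- 5
  v1 <- apply(sim$expr[, 1:4], 1, var)
  v2 <- apply(sim$expr[, 5:9], 1, var)
  s2 <- (3 * v1 + 4 * v2) / 7
  pooled_t <- (rowMeans(sim$expr[, 1:4]) - rowMeans(sim$expr[, 5:9])) /
    sqrt(s2 * (1 / k1 + 1 / k2))
  expect_equal(none$t, unname(pooled_t), tolerance = 1e-12)

  # d0 = Inf: every posterior variance is the prior variance
  full <- moderated_t(sim$expr, sim$design, d0 = Inf, s0_sq = 0.7)
  expect_true(all(full$s2_post == 0.7))

  # the shrinkage formula itself
  expect_equal(posterior_var(1, 4, 4, 0.25), 0.625)
  expect_true(all(full$p_value > 0 & full$p_value <= 1))
})

test_that("moderated t matches limma's empirical-Bayes pipeline", {
  sim <- simulate_expression(sim_config(300, 5, 5, deg_fraction = 0.1,
                                        seed = 12))
  mine <- moderated_t(sim$expr, sim$design)
  dm <- cbind(1, sim$design$group == "case")
  fit <- limma::eBayes(limma::lmFit(sim$expr, dm))
  expect_equal(mine$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(mine$p_value, unname(fit$p.value[, 2]), tolerance = 1e-8)
  expect_equal(attr(mine, "d0"), fit$df.prior, tolerance = 1e-6)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "within")

  set.seed(3)
  for (i in 1:500) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("welch p-values are uniform under the null", {
  sim <- simulate_expression(sim_config(2000, 5, 5, deg_fraction = 0,
                                        seed = 1))
  res <- welch_t(sim$expr, sim$design)
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(2000))  # 1% critical value
})

test_that("fold change follows the signed convention", {
  fx <- two_group_expr(c(3, 3), c(2, 2))
  fc <- fold_change(fx$expr, fx$design)
  expect_equal(fc$log2_fc, 1)
  expect_equal(fc$signed_fc, 2)

  fx2 <- two_group_expr(c(2, 2), c(3, 3))
  expect_equal(fold_change(fx2$expr, fx2$design)$signed_fc, -2)

  fx3 <- two_group_expr(c(2, 4), c(1, 5))
  expect_equal(fold_change(fx3$expr, fx3$design)$signed_fc, 1)
})
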