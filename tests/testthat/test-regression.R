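test_that("bootstrap plan applies the frequency and iteration-count laws", {
  p <- plan_bootstrap(500, 10, 1000)
  expect_equal(p$expected_frequency, 20)

  p2 <- plan_bootstrap(500, 10)
  expect_equal(p2$iterations, 2500)
  expect_equal(p2$expected_frequency, 50)

  # boundary: G = N means every feature in every iteration, f = B
  p3 <- plan_bootstrap(20, 20, 7)
  expect_equal(p3$expected_frequency, 7)

  expect_error(plan_bootstrap(10, 11), "exceeds")
})

test_that("group sampling redraws over-correlated groups and respects P = 1", {
  set.seed(1)
  n <- 60
  x <- cbind(a = stats::rlnorm(n), b = stats::rlnorm(n),
             c = stats::rlnorm(n))
  x <- cbind(x, d = x[, "a"])  # a/d is a flagged pair
  rownames(x) <- paste0("s", seq_len(n))

  # P = 1 disables the filter: the draw equals a plain seeded sample
  plan <- plan_bootstrap(4, 2, 10, corr_fraction = 1, seed = 99)
  g <- sample_group(plan, 3, x, colnames(x))
  set.seed(prognosig:::iter_seed(99L, 3))
  expect_equal(g, sort(sample(sort(colnames(x)), 2)))

  # P = 0: the duplicated pair can never be accepted
  plan0 <- plan_bootstrap(4, 2, 10, corr_fraction = 0, seed = 7)
  for (b in 1:25) {
    g <- sample_group(plan0, b, x, colnames(x))
    expect_false(setequal(g, c("a", "d")))
  }
})

test_that("selection counts follow the binomial inclusion law", {
  n_feat <- 50
  g <- 10
  b <- 200
  feats <- sprintf("f%03d", seq_len(n_feat))
  plan <- plan_bootstrap(n_feat, g, b, corr_fraction = 1, seed = 5)
  counts <- stats::setNames(rep(0, n_feat), feats)
  for (it in seq_len(b)) {
    set.seed(prognosig:::iter_seed(plan$seed, it))
    grp <- sample(feats, g)
    counts[grp] <- counts[grp] + 1
  }
  pr <- g / n_feat
  expect_equal(mean(counts), b * pr)  # exact: every draw places G features
  se_var <- sqrt(2 / (n_feat - 1)) * b * pr * (1 - pr)
  expect_lt(abs(stats::var(counts) - b * pr * (1 - pr)), 3 * se_var)
})

test_that("forced-lambda fits reproduce full shrinkage and the unpenalized oracle", {
  co <- generate_cohort(50, 3, true_effects = c(g0001 = 0.6), seed = 21,
                        censoring = 0.2)
  x <- log2(co$expr + 1)

  big <- fit_lasso_cox(x, co$surv, lambda = 50)
  expect_true(all(big$coefficients == 0))

  fit0 <- fit_lasso_cox(x, co$surv, lambda = 0)
  beta_oracle <- oracle_cox(x, co$surv$time, co$surv$status)
  expect_equal(unname(fit0$coefficients), unname(beta_oracle),
               tolerance = 1e-5)
})

test_that("cross-validated LASSO shrinks more coefficients to zero than Ridge", {
  co <- generate_cohort(60, 12, true_effects = c(g0001 = 0.8), seed = 31)
  set.seed(1)
  foldid <- prognosig:::stratified_folds(co$surv$status, 10)
  l1 <- fit_lasso_cox(co$expr, co$surv, penalty = "lasso", foldid = foldid)
  l2 <- fit_lasso_cox(co$expr, co$surv, penalty = "ridge", foldid = foldid)
  expect_gt(mean(l1$coefficients == 0), mean(l2$coefficients == 0))
  expect_equal(mean(l2$coefficients == 0), 0)
})

test_that("a degenerate one-group bootstrap equals its single fit", {
  co <- generate_cohort(50, 25, true_effects = c(g0001 = 0.8), seed = 41)
  plan <- plan_bootstrap(25, 25, 1, corr_fraction = 1, seed = 11)
  sig <- suppressWarnings(run_bootstrap_regression(co$expr, co$surv, plan))
  set.seed(prognosig:::iter_seed(11L, 1))
  grp <- sort(sample(sort(colnames(co$expr)), 25))  # replay the group draw
  fit <- fit_lasso_cox(co$expr[, grp], co$surv)
  expect_equal(stats::setNames(sig$coefficient, sig$feature)[sig$feature],
               fit$coefficients[sig$feature])
  expect_true(all(sig$times_sampled == 1))
})

test_that("signature fits are deterministic and feature-order invariant", {
  co <- generate_cohort(60, 25, true_effects = c(g0001 = 0.8, g0002 = -0.8),
                        seed = 51)
  fit1 <- suppressWarnings(prognosig(co$expr, co$surv, group_size = 5,
                                     iterations = 20, seed = 3))
  fit2 <- suppressWarnings(prognosig(co$expr, co$surv, group_size = 5,
                                     iterations = 20, seed = 3))
  expect_identical(fit1$signature, fit2$signature)

  perm <- sample(ncol(co$expr))
  fit3 <- suppressWarnings(prognosig(co$expr[, perm], co$surv,
                                     group_size = 5, iterations = 20,
                                     seed = 3))
  expect_identical(fit1$signature, fit3$signature)

  fit4 <- suppressWarnings(prognosig(co$expr, co$surv, group_size = 5,
                                     iterations = 20, seed = 4))
  expect_false(identical(fit1$signature, fit4$signature))
})

test_that("small cohorts fall back to a single regression", {
  co <- generate_cohort(40, 12, true_effects = c(g0001 = 0.9), seed = 61)
  fit <- suppressWarnings(prognosig(co$expr, co$surv, seed = 2))
  expect_equal(fit$decision, "single-regression")
  expect_true(all(fit$signature$times_sampled == 1))

  co2 <- generate_cohort(9, 30, seed = 62)
  expect_error(suppressWarnings(prognosig(co2$expr, co2$surv)), "rejected")
})

test_that("signature filtering keeps |coefficient| >= cutoff, order intact", {
  sig <- cox_signature(c("a", "b", "c"), c(0.05, -0.04, 0.01))
  expect_identical(filter_signature(sig, 0), sig)
  f <- filter_signature(sig, 0.035)
  expect_equal(f$feature, c("a", "b"))
  expect_error(filter_signature(sig, 10), "lower cutoff")

  # percentile cutoff agrees with a brute-force count
  set.seed(77)
  cf <- stats::rnorm(40)
  sig2 <- cox_signature(sprintf("f%02d", 1:40), cf)
  q <- stats::quantile(abs(cf), 0.9)
  expect_equal(nrow(filter_signature(sig2, q)), sum(abs(cf) >= q))
})

test_that("coef/predict methods expose the signature and risk scores", {
  co <- generate_cohort(50, 22, true_effects = c(g0001 = 0.8), seed = 71)
  fit <- suppressWarnings(prognosig(co$expr, co$surv, group_size = 5,
                                    iterations = 15, seed = 6))
  cf <- coef(fit)
  expect_named(cf)
  sc <- predict(fit, co$expr)
  manual <- drop(co$expr[, names(cf)] %*% cf)
  expect_equal(unname(sc), unname(manual), tolerance = 1e-12)
})
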