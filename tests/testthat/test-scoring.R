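test_that("risk scores are the coefficient-expression dot product and are linear", {
  co <- tiny_cohort(n = 10, p = 3, seed = 15)
  sig0 <- cox_signature(colnames(co$expr), rep(0, 3),
                        times_nonzero = c(0L, 0L, 0L))
  expect_true(all(compute_risk_score(co$expr, sig0) == 0))

  one <- matrix(3, 1, 1, dimnames = list("s1", "gX"))
  sig1 <- cox_signature("gX", 2)
  expect_equal(unname(compute_risk_score(one, sig1)), 6)

  set.seed(2)
  cf <- stats::rnorm(3)
  sig <- cox_signature(colnames(co$expr), cf)
  sc <- compute_risk_score(co$expr, sig)
  brute <- vapply(seq_len(nrow(co$expr)), function(i)
    sum(cf * co$expr[i, sig$feature]), numeric(1))
  expect_equal(unname(sc), brute, tolerance = 1e-12)

  # linearity in the coefficients
  sig3 <- cox_signature(sig$feature, 3 * sig$coefficient)
  expect_equal(compute_risk_score(co$expr, sig3), 3 * sc, tolerance = 1e-12)

  sig_bad <- cox_signature(c(sig$feature, "missing_gene"), c(cf, 1))
  expect_error(compute_risk_score(co$expr, sig_bad), "missing_gene")
})

test_that("median stratification puts scores at or below the cutoff in 'low'", {
  sc <- stats::setNames(c(1, 2, 3, 4), paste0("s", 1:4))
  st <- stratify(sc)
  expect_equal(st$group, c("low", "low", "high", "high"))
  expect_equal(attr(st, "cutoff"), 2.5)

  expect_error(stratify(stats::setNames(rep(1, 5), paste0("s", 1:5))),
               "identical")
})

test_that("ROC/Youden cutoff matches the exhaustive threshold scan", {
  set.seed(33)
  n <- 60
  status <- stats::rbinom(n, 1, 0.5)
  score <- stats::rnorm(n, mean = status)

  exact <- roc_youden_cutoff(score, status, smooth = FALSE)
  oracle <- oracle_youden(score, status)
  expect_equal(exact$youden_j, oracle$youden_j, tolerance = 1e-12)
  expect_equal(exact$cutoff, oracle$cutoff, tolerance = 1e-12)

  # smoothed cutoff stays within the NNE-style smoothing tolerance
  sm <- roc_youden_cutoff(score, status, smooth = TRUE)
  h <- stats::sd(score) * n^(-1 / 5)
  expect_lt(abs(sm$cutoff - oracle$cutoff), 4 * h)

  # perfect separation: J = 1 with the cutoff between the blocks
  sep_score <- c(1:5, 11:15)
  sep_status <- rep(c(0, 1), each = 5)
  perfect <- roc_youden_cutoff(sep_score, sep_status, smooth = FALSE)
  expect_equal(perfect$youden_j, 1)
  expect_gt(perfect$cutoff, 5)
  expect_lt(perfect$cutoff, 11)
})

test_that("score PH check warns on degenerate and PH-violating scores", {
  co <- tiny_cohort(n = 50, p = 3, seed = 17)
  const <- stats::setNames(rep(1, 50), co$surv$sample)
  expect_warning(res <- score_schoenfeld_check(const, co$surv),
                 "degenerate")
  expect_false(res$ok)

  # strongly time-varying effect triggers the warning path
  tv <- tv_effect_surv(n = 300, seed = 5)
  sv <- as_surv(tv$time, tv$status)
  sc <- stats::setNames(tv$x, sv$sample)
  expect_warning(res2 <- score_schoenfeld_check(sc, sv),
                 "proportional-hazards")
  expect_lt(res2$p, 0.05)
})

test_that("log-rank test matches hand arithmetic and is label-invariant", {
  same <- list(time = rep(c(10, 20, 30), 2), status = rep(1, 6),
               group = rep(c("low", "high"), each = 3))
  res <- logrank_test(same$time, same$status, same$group)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)

  # interleaved 6-sample toy against the O-E/V oracle
  time <- c(1, 3, 5, 2, 4, 6)
  status <- rep(1, 6)
  group <- rep(c("low", "high"), each = 3)
  res2 <- logrank_test(time, status, group)
  orc <- oracle_logrank(time, status, group)
  expect_equal(res2$statistic, orc$statistic, tolerance = 1e-10)
  expect_equal(res2$p, orc$p, tolerance = 1e-10)

  # random fixture with censoring and ties
  set.seed(3)
  t2 <- sample(1:40, 60, replace = TRUE)
  s2 <- stats::rbinom(60, 1, 0.6)
  g2 <- sample(c("low", "high"), 60, replace = TRUE)
  res3 <- logrank_test(t2, s2, g2)
  orc3 <- oracle_logrank(t2, s2, g2)
  expect_equal(res3$statistic, orc3$statistic, tolerance = 1e-10)

  # relabeling the groups changes nothing
  flipped <- ifelse(g2 == "low", "high", "low")
  expect_equal(logrank_test(t2, s2, flipped)$statistic, res3$statistic,
               tolerance = 1e-12)

  expect_error(logrank_test(t2, s2, rep("low", 60)), "two")
})

test_that("Kaplan-Meier estimates match the product-limit oracle", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$curve$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(km$median, 2)

  km2 <- km_estimate(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(km2$curve$surv == 1))
  expect_true(is.na(km2$median))

  set.seed(9)
  t3 <- sample(1:30, 80, replace = TRUE)
  s3 <- stats::rbinom(80, 1, 0.7)
  km3 <- km_estimate(t3, s3)
  orc <- oracle_km(t3, s3)
  got <- km3$curve[km3$curve$n_event > 0, ]
  expect_equal(got$surv, orc$surv, tolerance = 1e-12)
  expect_equal(km3$median, oracle_km_median(t3, s3))

  # survival probabilities start at 1 and never increase
  expect_true(all(diff(c(1, km3$curve$surv)) <= 1e-12))
})

test_that("univariate hazard ratios recover truth and match the Cox oracle", {
  # identical groups: HR ~ 1 with a covering CI
  set.seed(4)
  tt <- stats::rexp(200, 1 / 300)
  st <- stats::rbinom(200, 1, 0.7)
  gg <- rep(c("low", "high"), 100)
  res <- univariate_hr(tt, st, gg)
  expect_true(res$ci[1] <= 1 && 1 <= res$ci[2])

  # parameter recovery at beta = 0.7
  gs <- group_surv(400, 0.7, seed = 12, censor_at = 1500)
  res2 <- univariate_hr(gs$time, gs$status, gs$group, invert = TRUE)
  fit <- survival::coxph(
    survival::Surv(gs$time, gs$status) ~ factor(gs$group, c("low", "high")))
  se <- sqrt(fit$var[1, 1])
  expect_lt(abs(log(res2$hr) - 0.7), 3 * se)

  # small tie-free fixture against the Newton-Raphson oracle
  ts <- toy_surv(n = 40, seed = 19)
  g <- rep(c("low", "high"), 20)
  res3 <- univariate_hr(ts$time, ts$status, g)
  beta <- oracle_cox(matrix(as.numeric(g == "low"), ncol = 1),
                     ts$time, ts$status)
  expect_equal(log(res3$hr), beta, tolerance = 1e-6)

  # a group without events is flagged non-estimable
  res4 <- univariate_hr(c(1, 2, 3, 4), c(1, 1, 0, 0),
                        c("low", "low", "high", "high"))
  expect_false(res4$estimable)
})

test_that("high-score group fares worse end-to-end when planted effects are positive", {
  co <- generate_cohort(200, 10,
                        true_effects = c(g0001 = 0.9, g0002 = 0.9),
                        censoring = 0.2, seed = 23)
  sig <- cox_signature(c("g0001", "g0002"), c(0.5, 0.5))
  ev <- suppressWarnings(
    evaluate_signature(sig, co$expr, co$surv, log2 = TRUE))

  # KM of the high group lies at or below the low group everywhere
  lo <- ev$km$low$curve
  hi <- ev$km$high$curve
  grid <- sort(unique(c(lo$time, hi$time)))
  s_at <- function(cv, t) {
    i <- findInterval(t, cv$time)
    c(1, cv$surv)[i + 1]
  }
  expect_true(all(s_at(hi, grid) <= s_at(lo, grid) + 1e-12))

  expect_lt(ev$hr$hr, 1)  # low-vs-high HR below 1: high score is worse
  expect_lt(ev$logrank$p, 0.01)
  expect_lt(ev$median_survival[["high"]], ev$median_survival[["low"]])

  # invert flag flips the hazard ratio
  ev2 <- suppressWarnings(evaluate_signature(sig, co$expr, co$surv,
                                             log2 = TRUE, invert_hr = TRUE))
  expect_equal(ev2$hr$hr, 1 / ev$hr$hr, tolerance = 1e-8)
})

test_that("roc-youden stratification runs end-to-end with a curve twin", {
  co <- generate_cohort(120, 6, true_effects = c(g0001 = 1),
                        censoring = 0.2, seed = 29)
  sig <- cox_signature("g0001", 1)
  ev <- suppressWarnings(evaluate_signature(sig, co$expr, co$surv,
                                            cutoff = "roc-youden",
                                            log2 = TRUE))
  expect_false(is.null(ev$roc))
  expect_true(all(c("low", "high") %in% ev$score_table$group))
  expect_equal(ev$cutoff_method, "roc-youden")
})
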