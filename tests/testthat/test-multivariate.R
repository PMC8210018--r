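test_that("univariate screening keeps strong covariates and drops constants", {
  gs <- group_surv(300, 1, seed = 31, censor_at = 2000)
  sv <- as_surv(gs$time, gs$status,
                driver = gs$group,
                flat = rep("x", 300),
                noise = stats::rnorm(300))
  expect_warning(sc <- univariate_screen(sv, threshold = 0.2),
                 "single level")
  expect_true("driver" %in% sc$kept)
  expect_true("flat" %in% sc$dropped)
  expect_lt(sc$pvalues[["driver"]], 1e-6)
})

test_that("the score-only multivariate model reduces to the univariate HR", {
  gs <- group_surv(200, 0.8, seed = 37, censor_at = 2000)
  sv <- as_surv(gs$time, gs$status)
  res <- fit_multivariate(sv, stats::setNames(gs$group, sv$sample))
  uni <- univariate_hr(gs$time, gs$status, gs$group)
  row <- res$terms[res$terms$covariate == "score" & !res$terms$reference, ]
  expect_equal(row$hr, uni$hr, tolerance = 1e-10)
  expect_equal(c(row$lower, row$upper), uni$ci, tolerance = 1e-10)
})

test_that("multivariate coefficients match the partial-likelihood oracle", {
  ts <- toy_surv(n = 60, seed = 41)
  set.seed(42)
  grp <- sample(c("low", "high"), 60, replace = TRUE)
  age <- stats::rnorm(60, 60, 10)
  sex <- sample(c("F", "M"), 60, replace = TRUE)
  sv <- as_surv(ts$time, ts$status, sex = sex, age = age)

  res <- fit_multivariate(sv, stats::setNames(grp, sv$sample),
                          c("sex", "age"))

  # rebuild the design matrix exactly as the model codes it
  ref_sex <- names(which.max(table(sex)))
  X <- cbind(score_low = as.numeric(grp == "low"),
             sex_other = as.numeric(sex != ref_sex),
             age = age)
  beta <- oracle_cox(X, ts$time, ts$status)
  tt <- res$terms[!res$terms$reference, ]
  got <- log(tt$hr[match(c("score", "sex", "age"), tt$covariate)])
  expect_equal(got, unname(beta), tolerance = 1e-6)

  # reference levels carry HR = 1 by construction
  expect_true(all(res$terms$hr[res$terms$reference] == 1))
})

test_that("a confounder correlated with the score attenuates its hazard ratio", {
  co <- generate_cohort(500, 5, true_effects = c(g0001 = 1, g0002 = 1),
                        censoring = 0.2, seed = 43)
  clin <- generate_clinical(co, confounder_cor = 0.8, seed = 43)
  sig <- cox_signature(c("g0001", "g0002"), c(0.6, 0.6))
  ev <- suppressWarnings(evaluate_signature(sig, co$expr, clin,
                                            log2 = TRUE))
  multi <- fit_multivariate(ev$surv, ev$score_table, "confounder")
  row <- multi$terms[multi$terms$covariate == "score" &
                       !multi$terms$reference, ]
  # adjusted log-HR moves toward the null
  expect_lt(abs(log(row$hr)), abs(log(ev$hr$hr)))
  conf <- multi$terms[multi$terms$covariate == "confounder", ]
  expect_gt(conf$hr, 1)
})

test_that("multivariate screening pipeline assembles forest-ready terms", {
  co <- generate_cohort(250, 5, true_effects = c(g0001 = 1),
                        censoring = 0.25, seed = 47)
  clin <- generate_clinical(co, confounder_cor = 0.6, seed = 47)
  sig <- cox_signature("g0001", 1)
  ev <- suppressWarnings(evaluate_signature(sig, co$expr, clin,
                                            log2 = TRUE))
  multi <- multivariate_analysis(ev, screen_threshold = 0.2)
  expect_true("confounder" %in% multi$screen$kept)
  expect_true("score" %in% multi$terms$covariate)
  expect_true(all(multi$screen$screened_out$p >= 0.2))
})

test_that("bootstrap covariable frequency applies the eligibility rules", {
  co <- generate_cohort(400, 4, true_effects = c(g0001 = 1),
                        censoring = 0.25, seed = 53)
  clin <- generate_clinical(co, imbalance = 0.1, confounder_cor = 0.7,
                            seed = 53)
  sig <- cox_signature("g0001", 1)
  ev <- suppressWarnings(evaluate_signature(sig, co$expr, clin,
                                            log2 = TRUE))
  fr <- bootstrap_covariable_frequency(ev$surv, ev$score_table,
                                       cycles = 30, seed = 9)
  # a 10%-minority categorical is ineligible in essentially every cycle
  expect_equal(fr$eligible_cycles[["rare_class"]], 0)
  expect_false("rare_class" %in% fr$plotted)
  # the score stays relevant; the confounder is eligible every cycle even
  # though the score group absorbs much of its signal
  expect_gte(fr$frequency[["score"]], 0.9)
  expect_equal(fr$eligible_cycles[["confounder"]], fr$cycles_run)
  expect_true(all(fr$frequency >= 0 & fr$frequency <= 1, na.rm = TRUE))

  # reproducibility under a fixed seed
  fr2 <- bootstrap_covariable_frequency(ev$surv, ev$score_table,
                                        cycles = 30, seed = 9)
  expect_identical(fr$frequency, fr2$frequency)
})

test_that("a planted strong covariable reaches >= 90% relevance frequency", {
  gs <- group_surv(400, 1, seed = 59, censor_at = 2000)
  set.seed(59)
  sv <- as_surv(gs$time, gs$status,
                driver = gs$group,
                noise = sample(c("a", "b"), 400, replace = TRUE))
  score <- stats::setNames(sample(c("low", "high"), 400, replace = TRUE),
                           sv$sample)
  fr <- bootstrap_covariable_frequency(sv, score, cycles = 100, seed = 13)
  expect_gte(fr$frequency[["driver"]], 0.9)
  expect_true("driver" %in% fr$plotted)
})

test_that("pure-noise covariables usually stay below the 25% plotting threshold", {
  # Chance dataset-level associations propagate into every resample, so a
  # null covariate occasionally exceeds the threshold; the typical (median)
  # frequency stays well below it.
  freqs <- vapply(seq_len(20), function(r) {
    set.seed(6000 + r)
    n <- 250
    tt <- stats::rexp(n, 1 / 400)
    sv <- as_surv(pmin(tt, 1500), as.numeric(tt <= 1500),
                  noise1 = sample(c("a", "b"), n, replace = TRUE),
                  noise2 = stats::rnorm(n))
    score <- stats::setNames(sample(c("low", "high"), n, replace = TRUE),
                             sv$sample)
    bootstrap_covariable_frequency(sv, score, cycles = 50,
                                   seed = 6000 + r)$frequency[["noise1"]]
  }, numeric(1))
  expect_lt(stats::median(freqs), 0.25)
  expect_gte(mean(freqs < 0.25), 0.5)
})

test_that("identity-resampling single cycle reduces to the plain fit indicator", {
  gs <- group_surv(200, 1, seed = 61, censor_at = 2000)
  set.seed(61)
  sv <- as_surv(gs$time, gs$status,
                driver = gs$group,
                noise = sample(c("a", "b"), 200, replace = TRUE))
  score <- stats::setNames(sample(c("low", "high"), 200, replace = TRUE),
                           sv$sample)
  fr <- bootstrap_covariable_frequency(sv, score, cycles = 1, seed = 3,
                                       resample = FALSE)
  direct <- fit_multivariate(sv, score, c("driver", "noise"))
  expect_equal(unname(fr$frequency[c("driver", "noise")]),
               unname(as.numeric(direct$block_p[c("driver", "noise")] < 0.05)))
})

test_that("complete-case filtering never drops rows without nulls", {
  co <- generate_cohort(150, 4, seed = 67)
  clin <- generate_clinical(co, missingness = 0.1, seed = 67)
  full_rows <- stats::complete.cases(clin[, covariate_names(clin)])
  d <- prognosig:::multivariate_frame(clin,
                                      stats::setNames(rep(c("low", "high"),
                                                          length.out = 150),
                                                      clin$sample),
                                      covariate_names(clin))
  cc <- stats::complete.cases(d)
  expect_true(all(cc[full_rows]))
})
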