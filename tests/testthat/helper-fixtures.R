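# Small fixtures built in code. Continuous times drawn from rexp/runif are
# almost surely tie-free, which keeps the Cox oracles exact.

# A tiny cohort with no planted effects.
tiny_cohort <- function(n = 30, p = 5, seed = 42, censoring = 0.3) {
  generate_cohort(n, p, censoring = censoring, seed = seed)
}

# Direct survival vectors for oracle comparisons (no ties).
toy_surv <- function(n = 8, seed = 7) {
  set.seed(seed)
  list(time = round(stats::rexp(n, 1 / 300), 3) + stats::runif(n, 0, 1),
       status = stats::rbinom(n, 1, 0.7))
}

# Survival times driven by a binary group with a known log hazard ratio.
group_surv <- function(n, beta, seed = 1, censor_at = Inf) {
  set.seed(seed)
  group <- rep(c("low", "high"), length.out = n)
  rate <- ifelse(group == "high", exp(beta), 1) / 500
  t_event <- stats::rexp(n, rate)
  time <- pmin(t_event, censor_at)
  status <- as.numeric(t_event <= censor_at)
  list(time = time, status = status, group = group)
}

# surv_table wrapper around bare vectors.
as_surv <- function(time, status, ids = NULL, ...) {
  if (is.null(ids)) ids <- sprintf("s%04d", seq_along(time))
  df <- data.frame(sample = ids, time = time, status = status,
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  survival_table(df)
}

# Subset a surv_table preserving its class.
surv_rows <- function(surv, idx) {
  out <- surv[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(surv)
  out
}

# Cohort with a time-reversing effect: the feature's log hazard flips sign
# at the median follow-up, a textbook proportional-hazards violation.
tv_effect_surv <- function(n = 300, seed = 1, beta = 1.5, t_flip = 300) {
  set.seed(seed)
  x <- stats::rnorm(n)
  # piecewise-constant hazard h(t) = h0 exp(sign(t < t_flip) beta x)
  h0 <- 1 / 500
  h1 <- h0 * exp(beta * x)
  h2 <- h0 * exp(-beta * x)
  t1 <- stats::rexp(n, h1)
  time <- ifelse(t1 < t_flip, t1, t_flip + stats::rexp(n, h2))
  list(x = x, time = time, status = rep(1, n))
}
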