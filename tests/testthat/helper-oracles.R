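# Independent brute-force oracles. These deliberately use plain loops and
# first-principles formulas, never the survival/glmnet code paths they check.

# Product-limit estimator by direct multiplication over event times.
oracle_km <- function(time, status) {
  ord <- order(time)
  time <- time[ord]
  status <- status[ord]
  times <- sort(unique(time[status == 1]))
  s <- 1
  out <- data.frame(time = times, surv = NA_real_)
  for (i in seq_along(times)) {
    t <- times[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & status == 1)
    s <- s * (1 - d / n_risk)
    out$surv[i] <- s
  }
  out
}

# Smallest event time with S(t) <= 0.5, NA if never reached.
oracle_km_median <- function(time, status) {
  km <- oracle_km(time, status)
  med <- km$time[km$surv <= 0.5]
  if (length(med) > 0) min(med) else NA_real_
}

# Two-group log-rank by the O-E / V arithmetic at each event time.
oracle_logrank <- function(time, status, group) {
  group <- as.character(group)
  g1 <- unique(group)[1]
  times <- sort(unique(time[status == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & status == 1)
    d1 <- sum(time == t & status == 1 & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- o_minus_e^2 / v
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# Newton-Raphson maximizer of the Cox partial likelihood (Breslow ties;
# fixtures used with it have no tied event times, where Breslow = Efron).
oracle_cox <- function(x, time, status, tol = 1e-10, max_iter = 50) {
  x <- as.matrix(x)
  p <- ncol(x)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    grad <- rep(0, p)
    hess <- matrix(0, p, p)
    eta <- drop(x %*% beta)
    w <- exp(eta)
    for (i in which(status == 1)) {
      risk <- which(time >= time[i])
      wr <- w[risk]
      sw <- sum(wr)
      xbar <- colSums(x[risk, , drop = FALSE] * wr) / sw
      grad <- grad + x[i, ] - xbar
      xc <- sweep(x[risk, , drop = FALSE], 2, xbar)
      hess <- hess + t(xc * wr) %*% xc / sw
    }
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Exhaustive Youden-J scan over midpoint thresholds (unsmoothed ROC).
oracle_youden <- function(score, status) {
  s <- sort(unique(score))
  thr <- c(s[1] - 1, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1)
  best_j <- -Inf
  best_t <- NA_real_
  for (t in thr) {
    sens <- sum(score > t & status == 1) / sum(status == 1)
    spec <- sum(score <= t & status == 0) / sum(status == 0)
    j <- sens + spec - 1
    if (j > best_j) {
      best_j <- j
      best_t <- t
    }
  }
  list(cutoff = best_t, youden_j = best_j)
}

# Two-pass sample variance.
oracle_var <- function(x) {
  m <- sum(x) / length(x)
  sum((x - m)^2) / (length(x) - 1)
}
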