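#' Compute per-sample risk scores from a signature
#'
#' The risk score of sample `s` is the linear combination
#' `sum_f C_f * E_{s,f}` of signature coefficients `C` and expression values
#' `E`. Every signature feature must be present in the expression matrix.
#'
#' @param expr Samples x features expression matrix.
#' @param sig A `cox_signature` (or data frame with `feature` and
#'   `coefficient`).
#' @return Named numeric vector of scores, one per sample.
#' @export
compute_risk_score <- function(expr, sig) {
  missing_f <- setdiff(sig$feature, colnames(expr))
  if (length(missing_f) > 0L)
    stop("signature feature(s) absent from expression data: ",
         paste(missing_f, collapse = ", "))
  score <- drop(expr[, sig$feature, drop = FALSE] %*% sig$coefficient)
  if (any(!is.finite(score)))
    stop("non-finite risk score(s) produced")
  stats::setNames(score, rownames(expr))
}

#' Stratify samples into low/high score groups
#'
#' With the default `"median"` method the cutoff is the sample median of the
#' scores; with `"roc-youden"` the cutoff maximizes Youden's
#' J = sensitivity + specificity - 1 for classifying event status, over a
#' kernel-smoothed ROC curve (set `smooth = FALSE` for the exact empirical
#' ROC). In both cases a sample is `"high"` iff its score exceeds the
#' cutoff; scores at or below the cutoff are `"low"`.
#'
#' @param score Named numeric vector of per-sample scores (>= 4 samples).
#' @param method `"median"` (default) or `"roc-youden"`.
#' @param surv A `surv_table` (required for `"roc-youden"`, where `status`
#'   is the binary outcome).
#' @param smooth Use the kernel-smoothed ROC (default TRUE).
#' @param bandwidth Smoothing bandwidth; default `sd(score) * n^(-1/5)`.
#' @return A data frame of class `score_table` with columns `sample`,
#'   `score`, `group`, and attributes `cutoff`, `cutoff_method`, and (for
#'   ROC) `roc` — the curve's data frame.
#' @export
stratify <- function(score, method = c("median", "roc-youden"),
                     surv = NULL, smooth = TRUE, bandwidth = NULL) {
  method <- match.arg(method)
  if (length(score) < 4L) stop("need at least 4 samples to stratify")
  if (diff(range(score)) == 0)
    stop("all scores identical; stratification impossible")
  roc <- NULL
  if (method == "median") {
    cutoff <- stats::median(score)
  } else {
    if (is.null(surv)) stop("roc-youden stratification needs survival data")
    stopifnot(all(names(score) %in% surv$sample))
    status <- surv$status[match(names(score), surv$sample)]
    yj <- roc_youden_cutoff(score, status, smooth = smooth,
                            bandwidth = bandwidth)
    cutoff <- yj$cutoff
    roc <- yj$roc
  }
  out <- data.frame(sample = names(score), score = as.numeric(score),
                    group = ifelse(score > cutoff, "high", "low"),
                    stringsAsFactors = FALSE)
  if (length(unique(out$group)) < 2L)
    stop("cutoff ", format(cutoff), " puts every sample in one group")
  attr(out, "cutoff") <- cutoff
  attr(out, "cutoff_method") <- method
  attr(out, "roc") <- roc
  class(out) <- c("score_table", "data.frame")
  out
}

#' ROC/Youden optimal cut-point for a score against a binary outcome
#'
#' Candidate cutoffs are the midpoints between consecutive sorted unique
#' scores (plus outer sentinels). For each cutoff `t`, sensitivity is the
#' fraction of events with score > t and specificity the fraction of
#' non-events with score <= t; the returned cutoff maximizes Youden's
#' J = sens + spec - 1 (smallest maximizer on ties). With `smooth = TRUE`
#' the indicator is replaced by a Gaussian kernel with bandwidth
#' `sd(score) * n^(-1/5)`, giving a smoothed ROC in the spirit of
#' nearest-neighbour ROC estimates.
#'
#' @param score Numeric scores.
#' @param status Binary outcome (1 = event).
#' @param smooth Smooth the ROC (default TRUE).
#' @param bandwidth Kernel bandwidth; default `sd(score) * n^(-1/5)`.
#' @return List with `cutoff`, `youden_j`, and `roc` (data frame with
#'   `threshold`, `sensitivity`, `specificity`, `youden_j`).
#' @export
roc_youden_cutoff <- function(score, status, smooth = TRUE,
                              bandwidth = NULL) {
  stopifnot(length(score) == length(status), all(status %in% c(0, 1)))
  if (sum(status == 1) == 0L || sum(status == 0) == 0L)
    stop("both outcome classes needed for a ROC curve")
  s <- sort(unique(score))
  thr <- c(s[1L] - 1, (s[-1L] + s[-length(s)]) / 2, s[length(s)] + 1)
  ev <- score[status == 1]
  ce <- score[status == 0]
  if (smooth) {
    n <- length(score)
    if (is.null(bandwidth)) bandwidth <- stats::sd(score) * n^(-1 / 5)
    if (bandwidth <= 0) bandwidth <- .Machine$double.eps
    sens <- vapply(thr, function(t)
      mean(stats::pnorm((ev - t) / bandwidth)), numeric(1))
    spec <- vapply(thr, function(t)
      mean(stats::pnorm((t - ce) / bandwidth)), numeric(1))
  } else {
    sens <- vapply(thr, function(t) mean(ev > t), numeric(1))
    spec <- vapply(thr, function(t) mean(ce <= t), numeric(1))
  }
  j <- sens + spec - 1
  best <- which.max(j)
  list(cutoff = thr[best],
       youden_j = j[best],
       roc = data.frame(threshold = thr, sensitivity = sens,
                        specificity = spec, youden_j = j))
}

#' Proportional-hazards check on the risk score
#'
#' Fits a univariate Cox model of survival on the continuous score and runs
#' the Schoenfeld-residual PH test. A p-value below `alpha` (or a
#' numerically degenerate fit) produces a prominent warning, but analysis
#' proceeds: the score is the object under test, not a covariate to drop.
#'
#' @param score Named numeric scores.
#' @param surv A `surv_table` covering the scored samples.
#' @param alpha Warning threshold (default 0.05).
#' @param transform Time transform for the test (default `"km"`).
#' @return List with `ok` (logical) and `p` (PH-test p-value, NA when the
#'   fit failed).
#' @export
score_schoenfeld_check <- function(score, surv, alpha = 0.05,
                                   transform = "km") {
  sv <- surv[match(names(score), surv$sample), , drop = FALSE]
  y <- survival::Surv(sv$time, sv$status)
  p <- ph_test_pvalue(y, as.numeric(score), transform)
  if (is.na(p)) {
    warning("score PH check: Cox fit degenerate; cannot test assumptions")
    return(list(ok = FALSE, p = NA_real_))
  }
  if (p < alpha)
    warning(sprintf(
      "score violates the proportional-hazards assumption (p = %.3g)", p))
  list(ok = p >= alpha, p = p)
}

#' Two-group log-rank test
#'
#' Unweighted (Mantel-Haenszel) log-rank chi-square on 1 degree of freedom,
#' comparing the survival distributions of the low and high score groups.
#'
#' @param time,status Survival outcome vectors.
#' @param group Two-level grouping vector.
#' @return List with `statistic` and `p`.
#' @export
logrank_test <- function(time, status, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop("log-rank test needs exactly two non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, status) ~ group)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' Kaplan-Meier estimate for one group
#'
#' Product-limit estimator of the survival function, with the median
#' survival defined as the smallest event time at which the curve drops to
#' 0.5 or below (NA when the curve never reaches 0.5).
#'
#' @param time,status Survival outcome vectors (>= 1 sample).
#' @return List with `curve` (data frame `time`, `n_risk`, `n_event`,
#'   `surv`) and `median` (days or NA).
#' @export
km_estimate <- function(time, status) {
  stopifnot(length(time) >= 1L, length(time) == length(status))
  sf <- survival::survfit(survival::Surv(time, status) ~ 1)
  curve <- data.frame(time = sf$time, n_risk = sf$n.risk,
                      n_event = sf$n.event, surv = sf$surv)
  med <- curve$time[curve$surv <= 0.5 & curve$n_event > 0]
  list(curve = curve,
       median = if (length(med) > 0L) min(med) else NA_real_)
}

#' Univariate hazard ratio between score groups
#'
#' Cox model on the binary group indicator. Following the convention that
#' the high-score group is the reference, the reported HR is the hazard of
#' the low group relative to the high group, so a protective low score
#' yields HR < 1. Set `invert = TRUE` for high-vs-low.
#'
#' @param time,status Survival outcome vectors.
#' @param group Vector with levels `"low"` and `"high"`.
#' @param invert Report high-vs-low instead (default FALSE).
#' @return List with `hr`, `ci` (length-2), `p`, and `estimable`.
#' @export
univariate_hr <- function(time, status, group, invert = FALSE) {
  group <- as.character(group)
  stopifnot(all(group %in% c("low", "high")))
  ev <- tapply(status, group, sum)
  if (any(is.na(ev)) || any(ev == 0))
    return(list(hr = NA_real_, ci = c(NA_real_, NA_real_), p = NA_real_,
                estimable = FALSE))
  ref <- if (invert) "low" else "high"
  g <- stats::relevel(factor(group, levels = c("low", "high")), ref = ref)
  fit <- survival::coxph(survival::Surv(time, status) ~ g)
  sm <- summary(fit)
  list(hr = unname(sm$conf.int[1L, "exp(coef)"]),
       ci = unname(sm$conf.int[1L, c("lower .95", "upper .95")]),
       p = unname(sm$coefficients[1L, "Pr(>|z|)"]),
       estimable = TRUE)
}

#' Evaluate a signature's survival impact
#'
#' The univariate survival pipeline: scores every sample with
#' [compute_risk_score()], checks the proportional-hazards assumption of
#' the score, stratifies the cohort at the median score (or an ROC/Youden
#' cutoff), and summarizes the low/high contrast with a log-rank test,
#' per-group Kaplan-Meier curves with median survival, and a univariate
#' hazard ratio.
#'
#' @param sig A `cox_signature` (or a `prognosig` fit, whose signature is
#'   used).
#' @param expr Samples x features expression matrix.
#' @param surv A `surv_table` sharing samples with `expr`.
#' @param cutoff `"median"` (default) or `"roc-youden"`.
#' @param alpha PH-warning threshold for the score (default 0.05).
#' @param log2 Apply `log2(x + 1)` to expression first (use the same choice
#'   as in the regression step).
#' @param smooth Kernel-smooth the ROC when `cutoff = "roc-youden"`.
#' @param invert_hr Report the hazard ratio as high-vs-low.
#' @return An object of class `sig_survival`: `score_table`, `cutoff`,
#'   `cutoff_method`, `schoenfeld`, `logrank`, `hr`, per-group `n`,
#'   `median_survival`, `km` (named list of KM estimates), `roc`.
#' @export
evaluate_signature <- function(sig, expr, surv,
                               cutoff = c("median", "roc-youden"),
                               alpha = 0.05, log2 = FALSE, smooth = TRUE,
                               invert_hr = FALSE) {
  cutoff <- match.arg(cutoff)
  if (inherits(sig, "prognosig")) sig <- sig$signature
  joined <- join_cohort(expr, surv)
  x <- joined$expr
  sv <- joined$surv
  if (log2) x <- log2(x + 1)
  score <- compute_risk_score(x, sig)
  schoen <- withCallingHandlers(
    score_schoenfeld_check(score, sv, alpha = alpha),
    warning = function(w) invokeRestart("muffleWarning"))
  st <- stratify(score, method = cutoff, surv = sv, smooth = smooth)
  grp <- st$group
  lr <- logrank_test(sv$time, sv$status, grp)
  hr <- univariate_hr(sv$time, sv$status, grp, invert = invert_hr)
  km <- lapply(split(seq_along(grp), grp), function(i)
    km_estimate(sv$time[i], sv$status[i]))
  out <- list(score_table = st,
              cutoff = attr(st, "cutoff"),
              cutoff_method = cutoff,
              schoenfeld = schoen,
              logrank = lr,
              hr = hr,
              n = vapply(split(grp, grp), length, 0L),
              median_survival = vapply(km, `[[`, numeric(1), "median"),
              km = km,
              roc = attr(st, "roc"),
              surv = sv)
  class(out) <- "sig_survival"
  out
}

#' @export
print.sig_survival <- function(x, ...) {
  cat("Signature survival evaluation (", x$cutoff_method, " cutoff = ",
      format(x$cutoff, digits = 4), ")\n", sep = "")
  cat("  n: low =", x$n[["low"]], "| high =", x$n[["high"]], "\n")
  cat("  median survival (days): low =",
      format(x$median_survival[["low"]]),
      "| high =", format(x$median_survival[["high"]]), "\n")
  if (isTRUE(x$hr$estimable))
    cat(sprintf("  HR (low vs high) = %.4g [%.4g-%.4g], p = %.3g\n",
                x$hr$hr, x$hr$ci[1], x$hr$ci[2], x$hr$p))
  else cat("  HR not estimable (a group has no events)\n")
  cat(sprintf("  log-rank: chi-square = %.4g, p = %.3g\n",
              x$logrank$statistic, x$logrank$p))
  if (!isTRUE(x$schoenfeld$ok))
    cat(sprintf("  WARNING: score PH assumption questionable (p = %.3g)\n",
                x$schoenfeld$p))
  invisible(x)
}

#' @export
summary.sig_survival <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Tabular summary of a survival evaluation
#'
#' One-row data frame with the numbers a survival TSV output carries:
#' cutoff, group sizes, median survival, hazard ratio with CI, log-rank
#' statistic and p-value, and the score PH-test p-value.
#'
#' @param x A `sig_survival` object.
#' @return A one-row data frame.
#' @export
survival_table_row <- function(x) {
  stopifnot(inherits(x, "sig_survival"))
  data.frame(cutoff_method = x$cutoff_method,
             cutoff = x$cutoff,
             n_low = x$n[["low"]],
             n_high = x$n[["high"]],
             median_low = x$median_survival[["low"]],
             median_high = x$median_survival[["high"]],
             hr = x$hr$hr,
             hr_lower = x$hr$ci[1],
             hr_upper = x$hr$ci[2],
             hr_p = x$hr$p,
             logrank_stat = x$logrank$statistic,
             logrank_p = x$logrank$p,
             schoenfeld_p = x$schoenfeld$p,
             stringsAsFactors = FALSE)
}
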