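#' Plan a bootstrap attribute-resampling run
#'
#' With `N` attributes and group size `G`, each of `B` iterations draws `G`
#' features without replacement, so a feature's expected selection count is
#' `f = B * G / N`. When `B` is omitted it is set to `ceiling((N / G)^2)`,
#' which makes the expected frequency `N / G` — the recommended coverage for
#' a stable signature.
#'
#' @param n_features Total attribute count `N`.
#' @param group_size Group size `G` per iteration (>= 2, <= `N`).
#' @param iterations Iteration count `B`; default `ceiling((N / G)^2)`.
#' @param corr_fraction Maximum tolerated fraction `P` of flagged correlated
#'   pairs per group, in [0, 1] (default 0.3).
#' @param seed Master RNG seed for the run.
#' @return A list of class `bootstrap_plan` with fields `n_features`,
#'   `group_size`, `iterations`, `corr_fraction`, `seed` and the expected
#'   per-attribute `expected_frequency`.
#' @export
plan_bootstrap <- function(n_features, group_size, iterations = NULL,
                           corr_fraction = 0.3, seed = 1L) {
  n_features <- as.integer(n_features)
  group_size <- as.integer(group_size)
  if (group_size > n_features)
    stop("group size (", group_size, ") exceeds feature count (",
         n_features, ")")
  stopifnot(group_size >= 2L, corr_fraction >= 0, corr_fraction <= 1)
  if (is.null(iterations))
    iterations <- as.integer(ceiling((n_features / group_size)^2))
  iterations <- as.integer(iterations)
  stopifnot(iterations >= 1L)
  out <- list(n_features = n_features,
              group_size = group_size,
              iterations = iterations,
              corr_fraction = corr_fraction,
              seed = as.integer(seed),
              expected_frequency = iterations * group_size / n_features)
  class(out) <- "bootstrap_plan"
  out
}

#' @export
print.bootstrap_plan <- function(x, ...) {
  cat("Bootstrap plan: B =", x$iterations, "iterations of G =",
      x$group_size, "features out of N =", x$n_features, "\n")
  cat("  expected per-attribute sampling frequency f = BG/N =",
      format(x$expected_frequency, digits = 4), "\n")
  cat("  correlated-pair tolerance P =", x$corr_fraction,
      "| seed =", x$seed, "\n")
  invisible(x)
}

# Deterministic per-iteration seed stream derived from the master seed.
iter_seed <- function(seed, iteration) {
  s <- (abs(as.numeric(seed)) * 69069 + as.numeric(iteration)) %% 2147483647
  as.integer(s) + 1L
}

#' Draw one bootstrap feature group
#'
#' Draws `G` distinct features uniformly at random; if the fraction of
#' Spearman-flagged pairs among the group's `choose(G, 2)` pairs exceeds the
#' plan's tolerance `P`, the whole group is redrawn (up to `max_retries`
#' times). Sampling operates on the lexicographically sorted feature names,
#' so results do not depend on input column order.
#'
#' @param plan A `bootstrap_plan`.
#' @param iteration Iteration index (seeds the draw together with the plan
#'   seed).
#' @param expr Expression matrix (used for the correlation filter).
#' @param features Candidate feature names.
#' @param rho_min,alpha Flagging thresholds (see [spearman_pair_flags()]).
#' @param max_retries Maximum redraw attempts (default 100).
#' @return Character vector of `G` features, or `NULL` when every retry drew
#'   an over-correlated group.
#' @export
sample_group <- function(plan, iteration, expr, features,
                         rho_min = 0.8, alpha = 0.05, max_retries = 100L) {
  set.seed(iter_seed(plan$seed, iteration))
  rank_matrix <- if (plan$corr_fraction < 1)
    rank_columns(expr[, features, drop = FALSE]) else NULL
  draw_group(sort(features), plan$group_size, plan$corr_fraction,
             rank_matrix = rank_matrix,
             n = nrow(expr), rho_min = rho_min, alpha = alpha,
             max_retries = max_retries)
}

# Column-wise average ranks; Pearson correlation of these equals Spearman.
rank_columns <- function(x) apply(x, 2L, rank)

# Core redraw loop over a precomputed rank matrix (fast path for the
# bootstrap); returns NULL when retries are exhausted.
draw_group <- function(features_sorted, g, p_max, rank_matrix, n,
                       rho_min, alpha, max_retries) {
  n_pairs <- choose(g, 2L)
  for (try in seq_len(max_retries + 1L)) {
    grp <- sort(sample(features_sorted, g))
    if (p_max >= 1)
      return(grp)
    rho <- suppressWarnings(stats::cor(rank_matrix[, grp, drop = FALSE]))
    pv <- spearman_pvals(rho, n)
    flagged <- sum(upper.tri(rho) & abs(rho) > rho_min & pv < alpha,
                   na.rm = TRUE)
    if (flagged / n_pairs <= p_max)
      return(grp)
  }
  NULL
}

#' Fit a penalized Cox model on one feature group
#'
#' Fits an L1- (LASSO, default) or L2- (Ridge) penalized Cox model. The
#' penalty weight is chosen by 10-fold cross-validated partial
#' log-likelihood over a 50-point geometric lambda grid spanning
#' `[lambda_max * 1e-3, lambda_max]`; folds are stratified by event status.
#' Predictors are standardized internally before penalization and
#' coefficients are reported back on the original expression scale.
#' Forcing `lambda = 0` fits the unpenalized Cox model instead.
#'
#' @param x Samples x features matrix restricted to the group (>= 2
#'   features for a penalized fit).
#' @param surv Matching `surv_table`.
#' @param penalty `"lasso"` (L1) or `"ridge"` (L2).
#' @param nfolds Cross-validation folds (default 10).
#' @param lambda Optional fixed penalty weight; `0` means unpenalized.
#' @param foldid Optional fold assignment (length `nrow(x)`), overriding the
#'   internal stratified assignment.
#' @return A list of class `lasso_fit`: `features`, `lambda`,
#'   `coefficients` (named, zeros allowed), `cv_folds`, `penalty`.
#' @export
fit_lasso_cox <- function(x, surv, penalty = c("lasso", "ridge"),
                          nfolds = 10L, lambda = NULL, foldid = NULL) {
  penalty <- match.arg(penalty)
  stopifnot(nrow(x) == nrow(surv), nrow(x) >= 10L)
  y <- survival::Surv(surv$time, surv$status)
  alpha <- if (penalty == "lasso") 1 else 0
  if (!is.null(lambda) && length(lambda) == 1L && lambda == 0) {
    cf <- stats::coef(survival::coxph(y ~ x))
    names(cf) <- colnames(x)
    return(structure(list(features = colnames(x), lambda = 0,
                          coefficients = cf, cv_folds = NA_integer_,
                          penalty = penalty),
                     class = "lasso_fit"))
  }
  if (!is.null(lambda)) {
    # descend a geometric path onto the requested lambda so the solution
    # there is fully converged (warm starts), then read it off the grid
    path <- exp(seq(log(lambda * 1e3), log(lambda), length.out = 30L))
    fit <- glmnet::glmnet(x, y, family = "cox", alpha = alpha,
                          lambda = path)
    cf <- as.numeric(stats::coef(fit, s = lambda))
    names(cf) <- colnames(x)
    return(structure(list(features = colnames(x), lambda = lambda,
                          coefficients = cf, cv_folds = NA_integer_,
                          penalty = penalty),
                     class = "lasso_fit"))
  }
  if (is.null(foldid)) foldid <- stratified_folds(surv$status, nfolds)
  cv <- suppressWarnings(
    glmnet::cv.glmnet(x, y, family = "cox", alpha = alpha,
                      foldid = foldid, nlambda = 50L,
                      lambda.min.ratio = 1e-3,
                      type.measure = "deviance"))
  cf <- as.numeric(stats::coef(cv, s = "lambda.min"))
  names(cf) <- colnames(x)
  structure(list(features = colnames(x), lambda = cv$lambda.min,
                 coefficients = cf, cv_folds = as.integer(max(foldid)),
                 penalty = penalty),
            class = "lasso_fit")
}

# Event-status-stratified fold assignment (uses the current RNG stream).
stratified_folds <- function(status, nfolds) {
  foldid <- integer(length(status))
  for (s in unique(status)) {
    idx <- which(status == s)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  foldid
}

#' Fit a prognostic signature by bootstrap LASSO Cox regression
#'
#' The main fitting function. Expression and survival data are joined on
#' shared samples, passed through the preflight filters (cohort viability,
#' endpoint variability, variance cutoff, univariate Schoenfeld screen), and
#' then fitted: with 20 or more surviving features, `iterations` bootstrap
#' draws of `group_size` features are each vetted for collinearity
#' (Spearman) and fitted with a cross-validated penalized Cox model; with
#' fewer features a single penalized regression is fitted instead. Each
#' feature's signature coefficient is the mean of its fitted coefficients
#' over the iterations that sampled it, zeros included, so features that
#' are usually shrunk away aggregate toward zero.
#'
#' @param expr Samples x features expression matrix (non-negative).
#' @param surv A `surv_table` sharing sample identifiers with `expr`.
#' @param group_size Features per bootstrap iteration (default 10).
#' @param iterations Bootstrap iterations; default `ceiling((N / G)^2)`.
#' @param corr_fraction Maximum tolerated fraction of correlated pairs per
#'   group before it is redrawn (default 0.3).
#' @param variance_cutoff Low-variance removal threshold (default 0.01).
#' @param schoenfeld_alpha Removal threshold of the univariate PH screen
#'   (default 0.05).
#' @param corr_rho,corr_alpha Spearman flagging thresholds (defaults 0.8 and
#'   0.05).
#' @param penalty `"lasso"` (default) or `"ridge"` (comparison mode).
#' @param seed Master RNG seed; identical data + parameters + seed give a
#'   bit-identical signature.
#' @param log2 Apply `log2(x + 1)` to the expression values first.
#' @param max_retries Redraw bound for over-correlated groups (default 100).
#' @param keep_fits Keep per-iteration coefficient vectors in the returned
#'   object (needed for shrinkage diagnostics; default TRUE).
#' @return An object of class `prognosig` with components `signature`
#'   (a [cox_signature()]), `plan`, `decision`, `filter_report`,
#'   `iteration_fits`, `skipped_iterations`, `n_samples`, `penalty`, `call`.
#' @seealso [evaluate_signature()] to test the signature on survival data.
#' @export
prognosig <- function(expr, surv, group_size = 10L, iterations = NULL,
                      corr_fraction = 0.3, variance_cutoff = 0.01,
                      schoenfeld_alpha = 0.05, corr_rho = 0.8,
                      corr_alpha = 0.05, penalty = c("lasso", "ridge"),
                      seed = 1L, log2 = FALSE, max_retries = 100L,
                      keep_fits = TRUE) {
  penalty <- match.arg(penalty)
  cl <- match.call()
  joined <- join_cohort(expr, surv)
  x <- joined$expr
  sv <- joined$surv
  if (log2) x <- log2(x + 1)

  viability <- check_cohort_viability(x, sv)
  if (viability$decision == "reject")
    stop("cohort rejected: ", viability$reason)
  endpoint <- endpoint_variability_check(sv)
  if (!endpoint$ok)
    stop("cohort rejected: ", endpoint$reason)

  vf <- variance_filter(x, variance_cutoff)
  ss <- schoenfeld_screen(vf$expr, sv, alpha = schoenfeld_alpha)
  if (length(ss$kept) == 0L)
    stop("Schoenfeld screen removed every feature")
  x2 <- vf$expr[, ss$kept, drop = FALSE]
  report <- filter_report(ncol(x), vf$removed, ss$removed,
                          cohort_ok = TRUE, reason = viability$reason)

  decision <- check_cohort_viability(x2, sv)$decision
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))

  if (decision == "single-regression") {
    set.seed(iter_seed(seed, 1L))
    fit <- fit_lasso_cox(x2, sv, penalty = penalty)
    sig <- aggregate_signature(list(fit$coefficients))
    plan <- NULL
    fits <- list(fit)
    skipped <- integer(0)
  } else {
    plan <- plan_bootstrap(ncol(x2), group_size, iterations,
                           corr_fraction, seed)
    boot <- run_bootstrap_iterations(x2, sv, plan, penalty, corr_rho,
                                     corr_alpha, max_retries, keep_fits)
    if (length(boot$coef_list) == 0L)
      stop("every bootstrap iteration was skipped; no signature produced")
    sig <- aggregate_signature(boot$coef_list)
    fits <- if (keep_fits) boot$fits else NULL
    skipped <- boot$skipped
  }

  out <- list(signature = sig,
              plan = plan,
              decision = decision,
              filter_report = report,
              iteration_fits = fits,
              skipped_iterations = skipped,
              n_samples = nrow(x2),
              penalty = penalty,
              seed = as.integer(seed),
              call = cl)
  class(out) <- "prognosig"
  out
}

#' Run the bootstrap regression on pre-filtered data
#'
#' The core resampling engine, assuming the preflight filters have already
#' been applied: for each of the plan's iterations, draw a feature group,
#' vet it for collinearity, fit the cross-validated penalized Cox model, and
#' aggregate each feature's coefficients (mean over the iterations that
#' sampled it, zeros included) into a signature.
#'
#' @param expr Samples x features expression matrix (filtered, joined).
#' @param surv Matching `surv_table`.
#' @param plan A [plan_bootstrap()] result with
#'   `n_features == ncol(expr)`.
#' @param penalty `"lasso"` or `"ridge"`.
#' @param corr_rho,corr_alpha Spearman flagging thresholds.
#' @param max_retries Redraw bound per iteration.
#' @return A [cox_signature()]; features never sampled are absent.
#' @export
run_bootstrap_regression <- function(expr, surv, plan,
                                     penalty = c("lasso", "ridge"),
                                     corr_rho = 0.8, corr_alpha = 0.05,
                                     max_retries = 100L) {
  penalty <- match.arg(penalty)
  stopifnot(plan$n_features == ncol(expr), nrow(expr) == nrow(surv))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  boot <- run_bootstrap_iterations(expr, surv, plan, penalty, corr_rho,
                                   corr_alpha, max_retries,
                                   keep_fits = FALSE)
  if (length(boot$coef_list) == 0L)
    stop("every bootstrap iteration was skipped; no signature produced")
  aggregate_signature(boot$coef_list)
}

# The bootstrap loop proper: deterministic per-iteration seed streams drive
# the group draw and the CV fold assignment.
run_bootstrap_iterations <- function(x, sv, plan, penalty, corr_rho,
                                     corr_alpha, max_retries, keep_fits) {
  features_sorted <- sort(colnames(x))
  rank_matrix <- if (plan$corr_fraction < 1) rank_columns(x) else NULL
  coef_list <- vector("list", plan$iterations)
  fits <- if (keep_fits) vector("list", plan$iterations) else NULL
  skipped <- integer(0)
  for (b in seq_len(plan$iterations)) {
    set.seed(iter_seed(plan$seed, b))
    grp <- draw_group(features_sorted, plan$group_size, plan$corr_fraction,
                      rank_matrix, nrow(x), corr_rho, corr_alpha,
                      max_retries)
    if (is.null(grp)) {
      skipped <- c(skipped, b)
      next
    }
    fit <- tryCatch(fit_lasso_cox(x[, grp, drop = FALSE], sv,
                                  penalty = penalty),
                    error = function(e) NULL)
    if (is.null(fit)) {
      skipped <- c(skipped, b)
      next
    }
    coef_list[[b]] <- fit$coefficients
    if (keep_fits) fits[[b]] <- fit
  }
  if (length(skipped) > 0L)
    warning(length(skipped), " of ", plan$iterations,
            " bootstrap iteration(s) skipped")
  keep <- !vapply(coef_list, is.null, TRUE)
  list(coef_list = coef_list[keep],
       fits = if (keep_fits) fits[keep] else NULL,
       skipped = skipped)
}

# Mean coefficient per feature over the iterations that sampled it (zeros
# included); never-sampled features are absent. Ordered by |coefficient|
# descending, ties broken lexicographically.
aggregate_signature <- function(coef_list) {
  all_cf <- unlist(coef_list)
  feats <- names(all_cf)
  mean_cf <- tapply(all_cf, feats, mean)
  n_sampled <- tapply(all_cf, feats, length)
  n_nonzero <- tapply(all_cf != 0, feats, sum)
  ord <- order(-abs(mean_cf), names(mean_cf))
  cox_signature(names(mean_cf)[ord], as.numeric(mean_cf)[ord],
                as.integer(n_sampled)[ord], as.integer(n_nonzero)[ord])
}

#' Filter a signature by absolute coefficient
#'
#' Retains entries with `|coefficient| >= cutoff`, preserving order. Useful
#' for refining a broad signature into a minimal one (e.g. a 0.035 cutoff).
#'
#' @param sig A `cox_signature`.
#' @param cutoff Non-negative absolute-coefficient cutoff.
#' @return The filtered `cox_signature`.
#' @export
filter_signature <- function(sig, cutoff) {
  stopifnot(cutoff >= 0)
  keep <- abs(sig$coefficient) >= cutoff
  if (!any(keep))
    stop("no signature entries with |coefficient| >= ", cutoff,
         "; try a lower cutoff")
  out <- sig[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(sig)
  out
}

#' Fraction of exactly-zero per-iteration coefficients
#'
#' Shrinkage diagnostic: across all bootstrap iteration fits, the fraction
#' of fitted coefficients that are exactly zero. An L1 penalty produces a
#' strictly larger fraction than an L2 penalty on the same data.
#'
#' @param fit A `prognosig` object fitted with `keep_fits = TRUE`.
#' @return Fraction in [0, 1].
#' @export
zero_fraction <- function(fit) {
  stopifnot(inherits(fit, "prognosig"))
  if (is.null(fit$iteration_fits))
    stop("refit with keep_fits = TRUE to compute the zero fraction")
  cf <- unlist(lapply(fit$iteration_fits, `[[`, "coefficients"))
  mean(cf == 0)
}

#' Per-iteration coefficients of a fitted signature
#'
#' @param fit A `prognosig` object fitted with `keep_fits = TRUE`.
#' @return Named numeric vector concatenating all per-iteration fitted
#'   coefficients.
#' @export
iteration_coefficients <- function(fit) {
  stopifnot(inherits(fit, "prognosig"))
  if (is.null(fit$iteration_fits))
    stop("refit with keep_fits = TRUE")
  unlist(lapply(fit$iteration_fits, `[[`, "coefficients"))
}

#' @export
print.prognosig <- function(x, ...) {
  cat("Bootstrap penalized Cox signature fit (", x$penalty, " penalty)\n",
      sep = "")
  cat("  mode: ", x$decision, " | samples: ", x$n_samples, "\n", sep = "")
  if (!is.null(x$plan))
    cat("  B = ", x$plan$iterations, ", G = ", x$plan$group_size,
        ", N = ", x$plan$n_features, " (f = ",
        format(x$plan$expected_frequency, digits = 4), ")\n", sep = "")
  cat("  signature size: ", nrow(x$signature), " feature(s)\n", sep = "")
  print(x$signature, n = 5L)
  invisible(x)
}

#' @export
summary.prognosig <- function(object, ...) {
  sig <- object$signature
  out <- list(decision = object$decision,
              n_samples = object$n_samples,
              n_features = nrow(sig),
              n_iterations_used = length(object$iteration_fits),
              n_skipped = length(object$skipped_iterations),
              coef_range = range(sig$coefficient),
              top = top_coefficients(sig, 10L),
              filter_report = object$filter_report)
  class(out) <- "summary.prognosig"
  out
}

#' @export
print.summary.prognosig <- function(x, ...) {
  cat("Signature of", x$n_features, "features from", x$n_samples,
      "samples (", x$decision, ")\n")
  cat("  iterations used:", x$n_iterations_used,
      "| skipped:", x$n_skipped, "\n")
  cat("  coefficient range: [",
      format(x$coef_range[1], digits = 4), ", ",
      format(x$coef_range[2], digits = 4), "]\n", sep = "")
  print(x$filter_report)
  cat("Top coefficients by magnitude:\n")
  print.data.frame(as.data.frame(x$top), row.names = FALSE)
  invisible(x)
}

#' @export
coef.prognosig <- function(object, ...) {
  stats::setNames(object$signature$coefficient, object$signature$feature)
}

#' Predict per-sample risk scores from a fitted signature
#'
#' @param object A `prognosig` fit.
#' @param newdata Samples x features expression matrix containing every
#'   signature feature.
#' @param ... Unused.
#' @return Named numeric vector of risk scores.
#' @export
predict.prognosig <- function(object, newdata, ...) {
  compute_risk_score(newdata, object$signature)
}
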