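#' Decide whether a cohort supports bootstrap regression
#'
#' Bootstrap resampling of feature groups needs at least 20 features;
#' smaller feature sets fall back to a single penalized regression. Fewer
#' than 10 samples cannot support the 10-fold cross-validation used to pick
#' the penalty, so such cohorts are rejected outright.
#'
#' @param expr Samples x features expression matrix (already joined).
#' @param surv Matching `surv_table`.
#' @param min_features Minimum feature count for bootstrap mode (default 20).
#' @param min_samples Minimum sample count (default 10).
#' @return List with `decision` (`"bootstrap"`, `"single-regression"` or
#'   `"reject"`) and a human-readable `reason`.
#' @export
check_cohort_viability <- function(expr, surv, min_features = 20L,
                                   min_samples = 10L) {
  n <- nrow(expr)
  p <- ncol(expr)
  if (n < min_samples)
    return(list(decision = "reject",
                reason = sprintf("minimum of %d samples required, got %d",
                                 min_samples, n)))
  if (p < min_features)
    return(list(decision = "single-regression",
                reason = sprintf("%d features < %d: single regression",
                                 p, min_features)))
  list(decision = "bootstrap",
       reason = sprintf("%d samples, %d features", n, p))
}

#' Check endpoint-status variability
#'
#' A cohort whose endpoint barely varies (almost all events, or almost all
#' censored) cannot support stable partial-likelihood fits; it is rejected
#' when either status count falls below `min_each`.
#'
#' @param surv A `surv_table`.
#' @param min_each Minimum count required of each status (default 2).
#' @return List with `ok` (logical) and `reason`.
#' @export
endpoint_variability_check <- function(surv, min_each = 2L) {
  n_event <- sum(surv$status == 1)
  n_cens <- sum(surv$status == 0)
  if (n_event < min_each || n_cens < min_each)
    return(list(ok = FALSE,
                reason = sprintf(
                  "endpoint not variable enough: %d events, %d censored (need >= %d each)",
                  n_event, n_cens, min_each)))
  list(ok = TRUE, reason = sprintf("%d events, %d censored", n_event, n_cens))
}

#' Remove low-variance features
#'
#' Features whose sample variance is strictly below `cutoff` are removed;
#' a feature sitting exactly at the cutoff is retained.
#'
#' @param expr Samples x features expression matrix.
#' @param cutoff Non-negative variance cutoff on the analysis scale
#'   (default 0.01).
#' @return List with the filtered `expr` and `removed` feature names.
#' @export
variance_filter <- function(expr, cutoff = 0.01) {
  stopifnot(cutoff >= 0)
  v <- apply(expr, 2L, stats::var)
  removed <- colnames(expr)[v < cutoff]
  if (length(removed) == ncol(expr))
    stop("variance filter removed every feature (cutoff = ", cutoff, ")")
  list(expr = expr[, setdiff(colnames(expr), removed), drop = FALSE],
       removed = removed)
}

#' Univariate Schoenfeld proportional-hazards screen
#'
#' Fits a univariate Cox model per feature and tests the proportional
#' hazards assumption through the correlation of scaled Schoenfeld residuals
#' with transformed time ([survival::cox.zph()]). Features with a PH-test
#' p-value below `alpha` are removed; features whose Cox fit fails
#' numerically are also removed, with a warning, rather than aborting the
#' screen.
#'
#' @param expr Samples x features expression matrix.
#' @param surv Matching `surv_table`.
#' @param alpha Removal threshold on the PH-test p-value (default 0.05).
#' @param transform Time transform for the test: `"km"` (Kaplan-Meier
#'   scaled, default), `"identity"`, `"rank"` or `"log"`.
#' @return List with `kept`, `removed` feature names and the named vector of
#'   `pvalues` (NA for failed fits).
#' @export
schoenfeld_screen <- function(expr, surv, alpha = 0.05, transform = "km") {
  stopifnot(nrow(expr) == nrow(surv))
  y <- survival::Surv(surv$time, surv$status)
  p <- vapply(colnames(expr), function(f) {
    ph_test_pvalue(y, expr[, f], transform)
  }, numeric(1))
  failed <- names(p)[is.na(p)]
  if (length(failed) > 0L)
    warning("Cox fit failed for ", length(failed),
            " feature(s); removed from the screen: ",
            paste(utils::head(failed, 5L), collapse = ", "))
  removed <- names(p)[is.na(p) | p < alpha]
  list(kept = setdiff(colnames(expr), removed),
       removed = removed,
       pvalues = p)
}

# PH-test p-value for one covariate; NA on any numerical failure.
ph_test_pvalue <- function(y, x, transform = "km") {
  out <- tryCatch({
    fit <- survival::coxph(y ~ x)
    z <- survival::cox.zph(fit, transform = transform, global = FALSE)
    unname(z$table[1L, "p"])
  }, error = function(e) NA_real_, warning = function(w) NA_real_)
  if (length(out) != 1L || !is.finite(out)) NA_real_ else out
}

#' Flag strongly rank-correlated feature pairs
#'
#' A pair is flagged when its absolute Spearman correlation exceeds
#' `rho_min` and the asymptotic t-test p-value falls below `alpha`. The
#' bootstrap sampler uses the flagged fraction among a group's pairs to
#' decide whether to redraw the group.
#'
#' @param expr Samples x features expression matrix.
#' @param features Features to test (default: all); at least 2.
#' @param rho_min Absolute correlation threshold (default 0.8).
#' @param alpha P-value threshold (default 0.05).
#' @return Data frame with columns `feature1`, `feature2`, `rho`, `p` for
#'   flagged pairs (zero rows when none).
#' @export
spearman_pair_flags <- function(expr, features = colnames(expr),
                                rho_min = 0.8, alpha = 0.05) {
  stopifnot(length(features) >= 2L, all(features %in% colnames(expr)))
  sub <- expr[, features, drop = FALSE]
  rho <- stats::cor(sub, method = "spearman")
  n <- nrow(sub)
  pr <- spearman_pvals(rho, n)
  idx <- which(upper.tri(rho) & abs(rho) > rho_min & pr < alpha,
               arr.ind = TRUE)
  data.frame(feature1 = features[idx[, 1L]],
             feature2 = features[idx[, 2L]],
             rho = rho[idx],
             p = pr[idx],
             stringsAsFactors = FALSE)
}

# Asymptotic t approximation for Spearman correlation p-values
# (matches cor.test(..., method = "spearman", exact = FALSE)).
spearman_pvals <- function(rho, n) {
  r <- pmin(pmax(rho, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tt), df = n - 2)
}

# Fraction of a group's C(G,2) pairs that are flagged.
flagged_pair_fraction <- function(expr, features, rho_min, alpha) {
  n_pairs <- choose(length(features), 2L)
  if (n_pairs == 0L) return(0)
  nrow(spearman_pair_flags(expr, features, rho_min, alpha)) / n_pairs
}

#' Assemble a filter report
#'
#' Audit trail for the preflight stage: which features the variance filter
#' and the Schoenfeld screen removed, and whether the cohort passed the
#' viability checks.
#'
#' @param n_features_in Feature count before filtering.
#' @param removed_low_variance,removed_schoenfeld Removed feature names.
#' @param cohort_ok Logical; did the cohort pass viability checks.
#' @param reason Reason string for `cohort_ok`.
#' @return A list of class `filter_report`.
#' @export
filter_report <- function(n_features_in, removed_low_variance,
                          removed_schoenfeld, cohort_ok, reason = "") {
  if (length(intersect(removed_low_variance, removed_schoenfeld)) > 0L)
    stop("removal lists must be disjoint")
  out <- list(n_features_in = as.integer(n_features_in),
              removed_low_variance = removed_low_variance,
              removed_schoenfeld = removed_schoenfeld,
              n_features_out = as.integer(n_features_in -
                length(removed_low_variance) - length(removed_schoenfeld)),
              cohort_ok = cohort_ok,
              reason = reason)
  class(out) <- "filter_report"
  out
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Preflight filter report\n")
  cat("  features in: ", x$n_features_in, "\n", sep = "")
  cat("  removed (low variance): ", length(x$removed_low_variance), "\n",
      sep = "")
  cat("  removed (Schoenfeld screen): ", length(x$removed_schoenfeld), "\n",
      sep = "")
  cat("  features out: ", x$n_features_out, "\n", sep = "")
  cat("  cohort: ", if (isTRUE(x$cohort_ok)) "ok" else "rejected",
      " (", x$reason, ")\n", sep = "")
  invisible(x)
}

#' Write removed features with reasons to TSV
#'
#' @param report A `filter_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  df <- data.frame(
    feature = c(report$removed_low_variance, report$removed_schoenfeld),
    reason = c(rep("low_variance", length(report$removed_low_variance)),
               rep("schoenfeld", length(report$removed_schoenfeld))),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
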