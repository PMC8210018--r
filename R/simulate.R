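#' Simulate an expression cohort with right-censored survival
#'
#' Generates a samples x features expression matrix (log-normal,
#' expression-like scale) together with Weibull proportional-hazards
#' survival times driven by a small set of "true" prognostic features
#' embedded among nulls. Supports collinear feature blocks (built from
#' shared latent factors, hitting a target Spearman correlation), planted
#' low-variance features, and administrative uniform censoring calibrated
#' to a target fraction.
#'
#' The hazard model is `h(t | z) = h0(t) * exp(sum_f beta_f z_f)` with `z`
#' the standardized latent Gaussian of each feature and `h0` a Weibull
#' baseline, so survival times are
#' `T = scale * (-log(U) / exp(lp))^(1 / shape)`.
#'
#' @param n_samples,n_features Cohort dimensions.
#' @param true_effects Named numeric vector of log-hazard coefficients;
#'   names must be feature identifiers (`"g0001"` style) or are assigned to
#'   the first features when unnamed.
#' @param collinear_blocks List of `list(size =, rho =)` blocks; block
#'   members are appended after the independent features and share a latent
#'   factor giving pairwise Spearman correlation about `rho`.
#' @param n_low_variance Number of additional near-constant features.
#' @param weibull_shape,weibull_scale Baseline Weibull parameters
#'   (defaults 1.2 and 800 days, a cancer-cohort-like follow-up scale).
#' @param censoring Target censoring fraction in [0, 1) (default 0.3).
#' @param meanlog,sdlog Log-normal expression scale (defaults 2 and 0.5).
#' @param seed RNG seed.
#' @return List with `expr` (matrix), `surv` (a `surv_table`), and `truth`
#'   (list: `beta`, `blocks`, `linear_predictor`, `event_time`,
#'   `censoring_fraction`).
#' @export
generate_cohort <- function(n_samples, n_features, true_effects = NULL,
                            collinear_blocks = list(), n_low_variance = 0L,
                            weibull_shape = 1.2, weibull_scale = 800,
                            censoring = 0.3, meanlog = 2, sdlog = 0.5,
                            seed = 1L) {
  stopifnot(n_samples >= 2L, n_features >= 1L,
            censoring >= 0, censoring < 1)
  n_block <- sum(vapply(collinear_blocks, `[[`, 0, "size"))
  if (n_block + n_low_variance > n_features)
    stop("blocks plus low-variance features exceed n_features")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  feats <- sprintf("g%04d", seq_len(n_features))
  z <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features,
              dimnames = list(sprintf("s%04d", seq_len(n_samples)), feats))

  # collinear blocks occupy the tail features (before low-variance ones)
  blocks <- list()
  pos <- n_features - n_low_variance - n_block
  for (bl in collinear_blocks) {
    rho_s <- bl$rho
    if (rho_s >= 1 || rho_s <= -1)
      stop("infeasible Spearman target rho = ", rho_s)
    # Pearson correlation of the latent Gaussians that yields the target
    # Spearman correlation for a bivariate normal
    r <- 2 * sin(pi * rho_s / 6)
    f <- stats::rnorm(n_samples)
    cols <- feats[pos + seq_len(bl$size)]
    for (cc in cols)
      z[, cc] <- sqrt(r) * f + sqrt(1 - r) * stats::rnorm(n_samples)
    blocks[[length(blocks) + 1L]] <- cols
    pos <- pos + bl$size
  }

  beta <- stats::setNames(numeric(n_features), feats)
  if (!is.null(true_effects)) {
    if (is.null(names(true_effects)))
      names(true_effects) <- feats[seq_along(true_effects)]
    if (!all(names(true_effects) %in% feats))
      stop("unknown features in true_effects")
    beta[names(true_effects)] <- true_effects
  }

  expr <- exp(meanlog + sdlog * z)
  if (n_low_variance > 0L) {
    lv <- feats[(n_features - n_low_variance + 1L):n_features]
    expr[, lv] <- matrix(
      pmax(0, 5 + stats::rnorm(n_samples * n_low_variance, sd = 0.01)),
      n_samples, n_low_variance)
    beta[lv] <- 0
  }

  lp <- drop(z %*% beta)
  u <- stats::runif(n_samples)
  event_time <- weibull_scale * (-log(u) / exp(lp))^(1 / weibull_shape)

  if (censoring > 0) {
    cmax <- calibrate_censoring(event_time, censoring)
    cens_time <- stats::runif(n_samples, 0, cmax)
    time <- pmin(event_time, cens_time)
    status <- as.numeric(event_time <= cens_time)
  } else {
    time <- event_time
    status <- rep(1, n_samples)
  }
  time <- pmax(time, 1e-6)

  surv <- survival_table(data.frame(sample = rownames(expr),
                                    time = time, status = status,
                                    stringsAsFactors = FALSE))
  list(expr = expr,
       surv = surv,
       truth = list(beta = beta, blocks = blocks, linear_predictor = lp,
                    event_time = event_time,
                    censoring_fraction = mean(status == 0)))
}

# With C ~ U(0, cmax), P(censored_i) = min(T_i / cmax, 1); solve for cmax so
# the expected censoring fraction hits the target.
calibrate_censoring <- function(event_time, target) {
  f <- function(cm) mean(pmin(event_time / cm, 1)) - target
  hi <- max(event_time) / max(target, 1e-6) * 2
  stats::uniroot(f, lower = min(event_time) * 1e-6, upper = hi)$root
}

#' Simulate clinical covariates for a cohort
#'
#' Emits a balanced binary covariate (`sex`), an optionally imbalanced
#' binary covariate (`rare_class`), a numeric covariate (`age`), and an
#' optional numeric confounder correlated with the cohort's true linear
#' predictor. Missing values are inserted completely at random per cell.
#'
#' @param cohort A [generate_cohort()] result.
#' @param imbalance Minority fraction of `rare_class` (default 0.5 =
#'   balanced; use e.g. 0.1 to trigger the 20%-minority exclusion).
#' @param confounder_cor Correlation of the `confounder` column with the
#'   true linear predictor (0 disables the column).
#' @param missingness Per-cell missingness probability (default 0).
#' @param seed RNG seed.
#' @return The cohort's `surv_table` with covariate columns appended.
#' @export
generate_clinical <- function(cohort, imbalance = 0.5, confounder_cor = 0,
                              missingness = 0, seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed + 1000L)
  surv <- cohort$surv
  n <- nrow(surv)
  surv$sex <- sample(c("F", "M"), n, replace = TRUE)
  surv$rare_class <- sample(c("common", "rare"), n, replace = TRUE,
                            prob = c(1 - imbalance, imbalance))
  surv$age <- round(stats::rnorm(n, 60, 10), 1)
  if (confounder_cor != 0) {
    lp <- scale(cohort$truth$linear_predictor)[, 1L]
    if (stats::sd(lp) == 0) lp <- stats::rnorm(n)
    surv$confounder <- confounder_cor * lp +
      sqrt(1 - confounder_cor^2) * stats::rnorm(n)
  }
  if (missingness > 0) {
    for (cc in covariate_names(surv)) {
      miss <- stats::runif(n) < missingness
      surv[[cc]][miss] <- NA
    }
  }
  class(surv) <- c("surv_table", "data.frame")
  surv
}
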