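#' Univariate screening of clinical covariates
#'
#' Each covariate is fitted in its own univariate Cox model (complete cases
#' for that covariate; categoricals dummy-coded against their most frequent
#' level) and kept when the model's Wald p-value falls below `threshold`.
#' Constant (single-level) covariates are dropped with a warning. The risk
#' score never goes through this screen: it always enters the final model,
#' being the object under test.
#'
#' @param surv A `surv_table` carrying the covariates.
#' @param covariates Covariate column names to screen (default: all).
#' @param threshold Univariate p-value threshold (default 0.2).
#' @return List with `kept`, `screened_out` (data frame `covariate`, `p`)
#'   and `dropped` (unusable covariates).
#' @export
univariate_screen <- function(surv, covariates = covariate_names(surv),
                              threshold = 0.2) {
  stopifnot(all(covariates %in% names(surv)))
  pvals <- stats::setNames(rep(NA_real_, length(covariates)), covariates)
  dropped <- character(0)
  for (cc in covariates) {
    v <- prep_covariate(surv[[cc]])
    keep_rows <- !is.na(v)
    if (is.factor(v) && nlevels(droplevels(v[keep_rows])) < 2L ||
        (!is.factor(v) && stats::var(v[keep_rows]) == 0)) {
      warning("covariate '", cc, "' has a single level; dropped")
      dropped <- c(dropped, cc)
      next
    }
    fit <- tryCatch(
      survival::coxph(survival::Surv(surv$time[keep_rows],
                                     surv$status[keep_rows]) ~ v[keep_rows]),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("univariate Cox fit failed for covariate '", cc, "'; dropped")
      dropped <- c(dropped, cc)
      next
    }
    pvals[cc] <- summary(fit)$waldtest[["pvalue"]]
  }
  tested <- setdiff(covariates, dropped)
  kept <- tested[pvals[tested] < threshold]
  list(kept = kept,
       screened_out = data.frame(
         covariate = setdiff(tested, kept),
         p = unname(pvals[setdiff(tested, kept)]),
         stringsAsFactors = FALSE),
       dropped = dropped,
       pvalues = pvals)
}

# Categorical covariates become factors with the most frequent level as
# reference; numerics pass through.
prep_covariate <- function(v) {
  if (is.numeric(v)) return(v)
  f <- factor(v)
  tab <- table(f)
  stats::relevel(f, ref = names(tab)[which.max(tab)])
}

#' Multivariate Cox model of the score adjusted for clinical covariates
#'
#' Joint Cox fit of the low/high score group and the given covariates on
#' complete-case rows. Reference levels (most frequent category; the
#' high-score group for the score) carry HR = 1 by construction and appear
#' as reference rows in the term table.
#'
#' @param surv A `surv_table` carrying the covariates.
#' @param group Named (by sample) or aligned vector with levels
#'   `"low"`/`"high"`, e.g. the `group` column of a [stratify()] result.
#' @param covariates Covariate column names to adjust for (may be empty, in
#'   which case the model reduces to the univariate score model).
#' @return Object of class `sig_multicox`: `terms` (data frame `covariate`,
#'   `level`, `hr`, `lower`, `upper`, `p`, `reference`), `block_p` (per-
#'   covariate Wald p), `model_n`, and the underlying `fit`.
#' @export
fit_multivariate <- function(surv, group, covariates = character(0)) {
  d <- multivariate_frame(surv, group, covariates)
  cc <- stats::complete.cases(d)
  d <- d[cc, , drop = FALSE]
  rhs <- paste(c("score", covariates), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time, status) ~", rhs))
  warn <- character(0)
  fit <- withCallingHandlers(
    tryCatch(survival::coxph(fml, data = d),
             error = function(e) stop("multivariate Cox fit failed: ",
                                      conditionMessage(e), call. = FALSE)),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(grepl("infinite|converge", warn)))
    stop("multivariate Cox fit degenerate (separation or non-convergence); ",
         "check covariates: ", paste(c("score", covariates), collapse = ", "))
  structure(list(terms = multicox_terms(fit, d, covariates),
                 block_p = block_wald_p(fit, d, covariates),
                 model_n = nrow(d),
                 fit = fit),
            class = "sig_multicox")
}

# Assemble the modelling frame: score group (reference = high) + prepared
# covariates, aligned on surv rows.
multivariate_frame <- function(surv, group, covariates) {
  if (inherits(group, "score_table")) {
    g <- group$group[match(surv$sample, group$sample)]
  } else if (!is.null(names(group))) {
    g <- unname(group[surv$sample])
  } else {
    stopifnot(length(group) == nrow(surv))
    g <- group
  }
  d <- data.frame(time = surv$time, status = surv$status,
                  score = factor(g, levels = c("high", "low")),
                  stringsAsFactors = FALSE)
  for (cc in covariates) d[[cc]] <- prep_covariate(surv[[cc]])
  d
}

# Per-term HR table, including HR = 1 reference rows for factors.
multicox_terms <- function(fit, d, covariates) {
  sm <- summary(fit)
  ci <- sm$conf.int
  co <- sm$coefficients
  rows <- list()
  for (cc in c("score", covariates)) {
    v <- d[[cc]]
    if (is.factor(v)) {
      ref <- levels(v)[1L]
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cc, level = ref, hr = 1, lower = NA_real_,
        upper = NA_real_, p = NA_real_, reference = TRUE,
        stringsAsFactors = FALSE)
      for (lv in levels(v)[-1L]) {
        nm <- paste0(cc, lv)
        rows[[length(rows) + 1L]] <- data.frame(
          covariate = cc, level = lv,
          hr = ci[nm, "exp(coef)"],
          lower = ci[nm, "lower .95"], upper = ci[nm, "upper .95"],
          p = co[nm, "Pr(>|z|)"], reference = FALSE,
          stringsAsFactors = FALSE)
      }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cc, level = "(continuous)",
        hr = ci[cc, "exp(coef)"],
        lower = ci[cc, "lower .95"], upper = ci[cc, "upper .95"],
        p = co[cc, "Pr(>|z|)"], reference = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Wald chi-square on each covariate's coefficient block (df = #terms).
block_wald_p <- function(fit, d, covariates) {
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  out <- stats::setNames(numeric(0), character(0))
  for (cc in c("score", covariates)) {
    v <- d[[cc]]
    nms <- if (is.factor(v)) paste0(cc, levels(v)[-1L]) else cc
    nms <- intersect(nms, names(cf))
    if (length(nms) == 0L) {
      out[cc] <- NA_real_
      next
    }
    b <- cf[nms]
    W <- tryCatch(drop(t(b) %*% solve(V[nms, nms, drop = FALSE]) %*% b),
                  error = function(e) NA_real_)
    out[cc] <- stats::pchisq(W, df = length(nms), lower.tail = FALSE)
  }
  out
}

#' @export
print.sig_multicox <- function(x, ...) {
  cat("Multivariate Cox model (n =", x$model_n, ")\n")
  tt <- x$terms
  tt$hr <- signif(tt$hr, 4)
  tt$lower <- signif(tt$lower, 4)
  tt$upper <- signif(tt$upper, 4)
  tt$p <- signif(tt$p, 3)
  print.data.frame(tt, row.names = FALSE)
  invisible(x)
}

#' Clinically adjusted evaluation of a signature score
#'
#' Runs the multivariate branch of the survival pipeline on an existing
#' univariate evaluation: screens clinical covariates univariately, then
#' fits the final multivariate Cox model of the score group adjusted for
#' the covariates that passed.
#'
#' @param eval_obj A `sig_survival` object from [evaluate_signature()].
#' @param covariates Covariates to consider (default: all columns of the
#'   evaluation's survival table beyond time/status).
#' @param screen_threshold Univariate p threshold (default 0.2).
#' @return A `sig_multicox` object with an extra `screen` component.
#' @export
multivariate_analysis <- function(eval_obj,
                                  covariates = covariate_names(eval_obj$surv),
                                  screen_threshold = 0.2) {
  stopifnot(inherits(eval_obj, "sig_survival"))
  sc <- univariate_screen(eval_obj$surv, covariates,
                          threshold = screen_threshold)
  out <- fit_multivariate(eval_obj$surv, eval_obj$score_table, sc$kept)
  out$screen <- sc
  out
}

#' Patient-oriented bootstrap of covariable relevance
#'
#' Repeatedly resamples patients with replacement and refits the
#' multivariate Cox model of the score group plus the clinical covariates
#' eligible in that cycle. A cycle is eligible when, after removing rows
#' with missing values in the tested covariates, (i) at least
#' `retain_min` (70%) of the original patients remain represented, and
#' (ii) at least `min_covariables` covariables are eligible — a categorical
#' covariate being eligible only when its minority-category frequency in
#' the cycle is at least `minority_min` (20%). A covariate counts as
#' relevant in a cycle when its Wald p-value is below `alpha`. After all
#' cycles, each covariate's relevance frequency is the fraction of its
#' eligible cycles in which it was relevant; covariates at or above
#' `plot_threshold` (25%) form the plotted list.
#'
#' @param surv A `surv_table` with clinical covariates.
#' @param group Score group assignment (see [fit_multivariate()]).
#' @param covariates Covariates to test (default: all).
#' @param cycles Number of bootstrap cycles (default 100).
#' @param retain_min Minimum fraction of distinct original patients that
#'   must survive null-removal in a cycle (default 0.7).
#' @param minority_min Minimum minority-category frequency for a
#'   categorical covariate to be eligible in a cycle (default 0.2).
#' @param min_covariables Minimum eligible covariables per cycle (default 2).
#' @param alpha Per-cycle relevance threshold (default 0.05).
#' @param plot_threshold Minimum frequency for the plotted list
#'   (default 0.25).
#' @param seed RNG seed.
#' @param resample Draw bootstrap resamples (default TRUE); `FALSE` runs
#'   every cycle on the original cohort (diagnostic mode).
#' @return Object of class `covar_freq`: `cycles_run` (eligible cycles),
#'   `frequency` (named, in [0,1]), `eligible_cycles`, `relevant_cycles`,
#'   `plotted`.
#' @export
bootstrap_covariable_frequency <- function(surv, group,
                                           covariates = covariate_names(surv),
                                           cycles = 100L, retain_min = 0.7,
                                           minority_min = 0.2,
                                           min_covariables = 2L,
                                           alpha = 0.05,
                                           plot_threshold = 0.25,
                                           seed = 1L, resample = TRUE) {
  stopifnot(length(covariates) >= 1L)
  n <- nrow(surv)
  tested <- c("score", covariates)
  eligible_ct <- stats::setNames(integer(length(tested)), tested)
  relevant_ct <- stats::setNames(integer(length(tested)), tested)
  cycles_run <- 0L
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  for (cyc in seq_len(cycles)) {
    set.seed(iter_seed(seed, cyc))
    idx <- if (resample) sample.int(n, n, replace = TRUE) else seq_len(n)
    sv <- surv[idx, , drop = FALSE]
    class(sv) <- class(surv)
    elig <- covariates[vapply(covariates, function(cc)
      covariate_eligible(sv[[cc]], minority_min), TRUE)]
    if (length(elig) < min_covariables) next
    keep <- stats::complete.cases(sv[, elig, drop = FALSE])
    # null-removal must leave at least retain_min of the cycle's data
    if (sum(keep) < retain_min * n) next
    sv2 <- sv[keep, , drop = FALSE]
    class(sv2) <- class(surv)
    res <- tryCatch(fit_multivariate(sv2, group, elig),
                    error = function(e) NULL)
    if (is.null(res)) next
    cycles_run <- cycles_run + 1L
    for (cc in c("score", elig)) {
      eligible_ct[cc] <- eligible_ct[cc] + 1L
      p <- res$block_p[[cc]]
      if (!is.na(p) && p < alpha) relevant_ct[cc] <- relevant_ct[cc] + 1L
    }
  }
  if (cycles_run == 0L)
    stop("no eligible bootstrap cycle; relax the eligibility filters or ",
         "check covariate missingness/balance")
  freq <- ifelse(eligible_ct > 0, relevant_ct / eligible_ct, NA_real_)
  names(freq) <- tested
  structure(list(cycles_run = cycles_run,
                 frequency = freq,
                 eligible_cycles = eligible_ct,
                 relevant_cycles = relevant_ct,
                 plotted = names(freq)[!is.na(freq) &
                                         freq >= plot_threshold]),
            class = "covar_freq")
}

# A covariate is usable in a cycle if, over its non-missing values, it has
# spread: categoricals need >= 2 levels with minority frequency >= the
# threshold; numerics must be non-constant.
covariate_eligible <- function(v, minority_min) {
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(FALSE)
  if (is.numeric(v)) return(stats::var(v) > 0)
  tab <- table(v)
  tab <- tab[tab > 0]
  length(tab) >= 2L && min(tab) / sum(tab) >= minority_min
}

#' @export
print.covar_freq <- function(x, ...) {
  cat("Covariable relevance over", x$cycles_run, "eligible bootstrap",
      "cycle(s)\n")
  df <- data.frame(covariable = names(x$frequency),
                   eligible = unname(x$eligible_cycles),
                   relevant = unname(x$relevant_cycles),
                   frequency = signif(unname(x$frequency), 3))
  print.data.frame(df, row.names = FALSE)
  cat("plotted (frequency >= 25%):",
      if (length(x$plotted)) paste(x$plotted, collapse = ", ") else "none",
      "\n")
  invisible(x)
}
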