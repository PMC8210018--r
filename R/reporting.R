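#' Top signature coefficients by magnitude
#'
#' The `n` entries with the largest absolute coefficient, for the lollipop
#' display. Ties at the boundary are broken by lexicographic feature order,
#' so the result is deterministic across runs.
#'
#' @param sig A `cox_signature` (non-empty).
#' @param n Number of entries (default 10; fewer returned when the
#'   signature is smaller).
#' @return A `cox_signature` with at most `n` rows, ordered by descending
#'   `|coefficient|`.
#' @export
top_coefficients <- function(sig, n = 10L) {
  stopifnot(nrow(sig) >= 1L)
  ord <- order(-abs(sig$coefficient), sig$feature)
  out <- sig[ord[seq_len(min(n, nrow(sig)))], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(sig)
  out
}

# Plot-data builders: every rendered figure has a TSV twin carrying exactly
# these numbers, and the TSV is written before any rendering is attempted.

km_plot_data <- function(eval_obj) {
  do.call(rbind, lapply(names(eval_obj$km), function(g) {
    cv <- eval_obj$km[[g]]$curve
    data.frame(group = g, cv, stringsAsFactors = FALSE)
  }))
}

schoenfeld_plot_data <- function(eval_obj) {
  sv <- eval_obj$surv
  score <- eval_obj$score_table$score[match(sv$sample,
                                            eval_obj$score_table$sample)]
  zph <- tryCatch({
    fit <- survival::coxph(survival::Surv(sv$time, sv$status) ~ score)
    survival::cox.zph(fit, transform = "km", global = FALSE)
  }, error = function(e) NULL)
  if (is.null(zph)) return(data.frame(time = numeric(0),
                                      residual = numeric(0)))
  data.frame(time = zph$x, residual = zph$y[, 1L])
}

covar_freq_data <- function(freq) {
  data.frame(covariable = names(freq$frequency),
             eligible = unname(freq$eligible_cycles),
             relevant = unname(freq$relevant_cycles),
             frequency = unname(freq$frequency),
             plotted = names(freq$frequency) %in% freq$plotted,
             stringsAsFactors = FALSE)
}

#' Write a full report bundle
#'
#' Writes the pipeline's textual outputs (signature TSV, survival TSV,
#' multivariate TSV) and, for every figure, a machine-readable TSV twin and
#' a rendered PNG. Numeric twins are written first; a rendering failure
#' never corrupts them. A manifest JSON listing every file with its MD5
#' checksum is written last.
#'
#' @param prefix Output path prefix; files are named
#'   `<prefix>.<artifact>.<ext>`.
#' @param fit Optional `prognosig` object (signature, lollipop, coefficient
#'   histogram).
#' @param eval_obj Optional `sig_survival` (survival TSV, KM, Schoenfeld,
#'   ROC).
#' @param multi Optional `sig_multicox` (multivariate TSV, forest plot).
#' @param freq Optional `covar_freq` (covariable-frequency histogram).
#' @param render Render PNG images (default TRUE); TSV twins are always
#'   written.
#' @return Invisibly, the manifest as a named list of files.
#' @export
write_run_report <- function(prefix, fit = NULL, eval_obj = NULL,
                             multi = NULL, freq = NULL, render = TRUE) {
  files <- character(0)
  add <- function(path) files <<- c(files, path)
  tsv <- function(df, what) {
    path <- paste0(prefix, ".", what, ".tsv")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    add(path)
    path
  }
  fig <- function(what, draw) {
    if (!render) return(invisible(NULL))
    path <- paste0(prefix, ".", what, ".png")
    ok <- tryCatch({
      grDevices::png(path, width = 900, height = 700, res = 120)
      on.exit(grDevices::dev.off(), add = TRUE)
      draw()
      TRUE
    }, error = function(e) {
      warning("rendering '", what, "' failed: ", conditionMessage(e))
      FALSE
    })
    if (ok) add(path)
  }

  if (!is.null(fit)) {
    sig_path <- paste0(prefix, ".signature.tsv")
    write_signature(fit$signature, sig_path)
    add(sig_path)
    top <- top_coefficients(fit$signature, 10L)
    tsv(as.data.frame(top), "lollipop")
    fig("lollipop", function() plot_lollipop(top))
    tsv(data.frame(coefficient = fit$signature$coefficient),
        "coefficient_histogram")
    fig("coefficient_histogram", function()
      plot_coefficient_histogram(fit$signature))
  }
  if (!is.null(eval_obj)) {
    tsv(survival_table_row(eval_obj), "survival")
    tsv(as.data.frame(eval_obj$score_table), "scores")
    tsv(km_plot_data(eval_obj), "kaplan_meier")
    fig("kaplan_meier", function() plot_km(eval_obj))
    sch <- schoenfeld_plot_data(eval_obj)
    tsv(sch, "schoenfeld")
    if (nrow(sch) > 0L)
      fig("schoenfeld", function() plot_schoenfeld(sch, eval_obj))
    if (!is.null(eval_obj$roc)) {
      tsv(eval_obj$roc, "roc")
      fig("roc", function() plot_roc(eval_obj))
    }
  }
  if (!is.null(multi)) {
    tsv(multi$terms, "multivariate")
    fig("forest", function() plot_forest(multi))
  }
  if (!is.null(freq)) {
    tsv(covar_freq_data(freq), "covariable_frequency")
    fig("covariable_frequency", function() plot_covar_freq(freq))
  }

  manifest <- lapply(files, function(f)
    list(file = basename(f), md5 = unname(tools::md5sum(f))))
  man_path <- paste0(prefix, ".manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE)
  invisible(c(files, man_path))
}

#' Lollipop plot of the top signature coefficients
#' @param top A `cox_signature`, typically from [top_coefficients()].
#' @return Invisibly, `top`.
#' @export
plot_lollipop <- function(top) {
  op <- graphics::par(mar = c(5, 8, 3, 2))
  on.exit(graphics::par(op))
  y <- rev(seq_len(nrow(top)))
  graphics::plot(top$coefficient, y, pch = 19, col = "steelblue",
                 xlab = "aggregated coefficient", ylab = "", yaxt = "n",
                 main = "Top signature coefficients",
                 xlim = range(c(0, top$coefficient)))
  graphics::segments(0, y, top$coefficient, y, col = "steelblue")
  graphics::abline(v = 0, lty = 2, col = "grey60")
  graphics::axis(2, at = y, labels = top$feature, las = 1, cex.axis = 0.8)
  invisible(top)
}

#' Histogram of signature coefficients
#' @param sig A `cox_signature`.
#' @return Invisibly, `sig`.
#' @export
plot_coefficient_histogram <- function(sig) {
  graphics::hist(sig$coefficient, breaks = 30, col = "grey80",
                 xlab = "aggregated coefficient", main =
                   "Signature coefficient distribution")
  invisible(sig)
}

#' Kaplan-Meier plot of the low/high score groups
#' @param eval_obj A `sig_survival` object.
#' @return Invisibly, `eval_obj`.
#' @export
plot_km <- function(eval_obj) {
  cols <- c(low = "forestgreen", high = "firebrick")
  xmax <- max(vapply(eval_obj$km, function(k) max(k$curve$time), 0))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = "follow-up time (days)",
                 ylab = "survival probability",
                 main = sprintf("Kaplan-Meier by score group (log-rank p = %.3g)",
                                eval_obj$logrank$p))
  for (g in names(eval_obj$km)) {
    cv <- eval_obj$km[[g]]$curve
    graphics::lines(stats::stepfun(cv$time, c(1, cv$surv)), col = cols[[g]],
                    do.points = FALSE, lwd = 2)
  }
  graphics::abline(h = 0.5, lty = 3, col = "grey70")
  graphics::legend("topright", bty = "n", lwd = 2, col = cols,
                   legend = sprintf("%s (n = %d)", names(cols),
                                    eval_obj$n[names(cols)]))
  # at-risk counts along the time axis
  at <- pretty(c(0, xmax), 4)
  for (i in seq_along(names(cols))) {
    g <- names(cols)[i]
    cv <- eval_obj$km[[g]]$curve
    risk <- vapply(at, function(t) {
      left <- cv$n_risk[cv$time >= t]
      if (length(left) > 0L) left[1L] else 0L
    }, numeric(1))
    graphics::mtext(paste(risk, collapse = "   "), side = 1, line = 2.6 + i,
                    cex = 0.7, col = cols[[g]], adj = 0)
  }
  invisible(eval_obj)
}

#' Scaled Schoenfeld residual plot for the score
#' @param sch Data frame from the Schoenfeld TSV twin (`time`, `residual`).
#' @param eval_obj The `sig_survival` object (for the p-value annotation).
#' @return Invisibly, `sch`.
#' @export
plot_schoenfeld <- function(sch, eval_obj = NULL) {
  p <- if (!is.null(eval_obj)) eval_obj$schoenfeld$p else NA
  graphics::plot(sch$time, sch$residual, pch = 1, col = "grey40",
                 xlab = "KM-transformed time",
                 ylab = "scaled Schoenfeld residual (score)",
                 main = sprintf("PH check on the score (p = %.3g)", p))
  graphics::lines(stats::lowess(sch$time, sch$residual), col = "firebrick",
                  lwd = 2)
  invisible(sch)
}

#' Forest plot of a multivariate Cox model
#' @param multi A `sig_multicox` object.
#' @return Invisibly, `multi`.
#' @export
plot_forest <- function(multi) {
  tt <- multi$terms
  lab <- paste0(tt$covariate, ": ", tt$level)
  y <- rev(seq_len(nrow(tt)))
  op <- graphics::par(mar = c(5, 12, 3, 2))
  on.exit(graphics::par(op))
  xr <- range(c(tt$hr, tt$lower, tt$upper), na.rm = TRUE)
  graphics::plot(tt$hr, y, log = "x", pch = 15, xlim = xr, yaxt = "n",
                 xlab = "hazard ratio (95% CI)", ylab = "",
                 main = sprintf("Multivariate Cox model (n = %d)",
                                multi$model_n))
  graphics::segments(tt$lower, y, tt$upper, y)
  graphics::abline(v = 1, lty = 2, col = "grey60")
  graphics::axis(2, at = y, labels = lab, las = 1, cex.axis = 0.8)
  invisible(multi)
}

#' ROC curve of the score against event status
#' @param eval_obj A `sig_survival` evaluated with the ROC/Youden cutoff.
#' @return Invisibly, `eval_obj`.
#' @export
plot_roc <- function(eval_obj) {
  roc <- eval_obj$roc
  if (is.null(roc)) stop("no ROC data; evaluate with cutoff = 'roc-youden'")
  graphics::plot(1 - roc$specificity, roc$sensitivity, type = "l", lwd = 2,
                 col = "steelblue", xlab = "1 - specificity",
                 ylab = "sensitivity",
                 main = sprintf("ROC of score vs event (cutoff = %.4g)",
                                eval_obj$cutoff))
  graphics::abline(0, 1, lty = 2, col = "grey60")
  best <- which.max(roc$youden_j)
  graphics::points(1 - roc$specificity[best], roc$sensitivity[best],
                   pch = 19, col = "firebrick")
  invisible(eval_obj)
}

#' Histogram of covariable relevance frequencies
#' @param freq A `covar_freq` object.
#' @return Invisibly, `freq`.
#' @export
plot_covar_freq <- function(freq) {
  df <- covar_freq_data(freq)
  df <- df[df$plotted, , drop = FALSE]
  if (nrow(df) == 0L) {
    graphics::plot.new()
    graphics::title("No covariable reached the 25% plotting threshold")
    return(invisible(freq))
  }
  graphics::barplot(df$frequency, names.arg = df$covariable,
                    col = "steelblue", ylim = c(0, 1),
                    ylab = "relevance frequency",
                    main = sprintf("Covariable relevance (%d cycles)",
                                   freq$cycles_run))
  graphics::abline(h = 0.25, lty = 2, col = "grey50")
  invisible(freq)
}

#' Plot method for a signature fit
#'
#' @param x A `prognosig` object.
#' @param type `"lollipop"` (default) or `"histogram"`.
#' @param ... Unused.
#' @return Invisibly, `x`.
#' @export
plot.prognosig <- function(x, type = c("lollipop", "histogram"), ...) {
  type <- match.arg(type)
  if (type == "lollipop") plot_lollipop(top_coefficients(x$signature, 10L))
  else plot_coefficient_histogram(x$signature)
  invisible(x)
}

#' Plot method for a survival evaluation (Kaplan-Meier)
#'
#' @param x A `sig_survival` object.
#' @param ... Unused.
#' @return Invisibly, `x`.
#' @export
plot.sig_survival <- function(x, ...) plot_km(x)
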