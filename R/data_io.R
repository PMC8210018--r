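#' Read an expression matrix from a TSV file
#'
#' Reads a tab-separated expression table (TPM/FPKM-scale, non-negative) into
#' a validated numeric matrix with samples in rows and features (genes or
#' transcripts) in columns. The file must have a header row; the first column
#' holds identifiers. Values are used as-is: the pipeline never transforms
#' expression unless \code{log2 = TRUE}, which applies \code{log2(x + 1)}.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param orientation Either \code{"samples-in-rows"} (default) or
#'   \code{"features-in-rows"}; the returned matrix always has samples in
#'   rows.
#' @param log2 Apply a \code{log2(x + 1)} transform after validation.
#' @return Numeric matrix, samples x features, with unique dimnames.
#' @export
read_expression <- function(path,
                            orientation = c("samples-in-rows",
                                            "features-in-rows"),
                            log2 = FALSE) {
  orientation <- match.arg(orientation)
  raw <- read_tsv_table(path)
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate row identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as_numeric_grid(raw, path)
  rownames(m) <- ids
  if (orientation == "features-in-rows") m <- t(m)
  m <- validate_expression(m)
  if (log2) m <- log2(m + 1)
  m
}

#' Write an expression matrix to TSV
#'
#' @param x Numeric samples x features matrix.
#' @param path Output file path.
#' @param orientation Row orientation to write (see [read_expression()]).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path,
                             orientation = c("samples-in-rows",
                                             "features-in-rows")) {
  orientation <- match.arg(orientation)
  x <- validate_expression(x)
  if (orientation == "features-in-rows") x <- t(x)
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- if (orientation == "samples-in-rows") "sample" else "feature"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate an expression matrix
#'
#' Checks the invariants the pipeline relies on: a numeric matrix with unique
#' sample and feature identifiers and finite, non-negative values.
#'
#' @param x Matrix to validate.
#' @return The validated matrix, invisibly usable downstream.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix needs sample rownames and feature colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate feature identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (any(!is.finite(x)))
    stop("expression matrix contains non-finite values")
  if (any(x < 0))
    stop("expression matrix contains negative values")
  x
}

#' Read a survival table from TSV
#'
#' The first column holds sample identifiers; \code{time_col} (positive
#' follow-up, days) and \code{status_col} (1 = event, 0 = censored) are
#' mandatory; every other column is kept as a clinical covariate. Missing
#' values are a hard error in time/status but allowed (and counted in a
#' message) in covariates.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param time_col,status_col Column names for follow-up time and event
#'   status.
#' @return A `data.frame` with columns `sample`, `time`, `status` and any
#'   covariates, of class `surv_table`.
#' @export
read_survival <- function(path, time_col = "time", status_col = "status") {
  raw <- read_tsv_table(path)
  if (!time_col %in% names(raw))
    stop("missing time column '", time_col, "' in ", path)
  if (!status_col %in% names(raw))
    stop("missing status column '", status_col, "' in ", path)
  ids <- as.character(raw[[1L]])
  covar_cols <- setdiff(names(raw)[-1L], c(time_col, status_col))
  out <- data.frame(sample = ids,
                    time = suppressWarnings(as.numeric(raw[[time_col]])),
                    status = suppressWarnings(as.numeric(raw[[status_col]])),
                    stringsAsFactors = FALSE)
  for (cc in covar_cols) out[[cc]] <- raw[[cc]]
  survival_table(out)
}

#' Construct and validate a survival table
#'
#' @param df Data frame with columns `sample`, `time`, `status`; extra
#'   columns are treated as clinical covariates.
#' @return The validated data frame with class `surv_table`.
#' @export
survival_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("sample", "time", "status")
  if (!all(need %in% names(df)))
    stop("survival table needs columns: ", paste(need, collapse = ", "))
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample))
    stop("duplicate sample identifiers: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  if (any(is.na(df$time)) || any(is.na(df$status)))
    stop("missing values in time/status are not allowed")
  if (any(df$time <= 0))
    stop("follow-up times must be strictly positive")
  if (!all(df$status %in% c(0, 1)))
    stop("status must be 0 (censored) or 1 (event)")
  covs <- setdiff(names(df), need)
  n_missing <- sum(vapply(df[covs], function(v) sum(is.na(v)), 0L))
  if (n_missing > 0L)
    message(n_missing, " missing covariate cell(s) retained as NA")
  df <- df[, c(need, covs), drop = FALSE]
  class(df) <- c("surv_table", "data.frame")
  df
}

#' Write a survival table to TSV
#'
#' @param surv A `surv_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survival <- function(surv, path) {
  utils::write.table(as.data.frame(surv), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Covariate columns of a survival table
#' @param surv A `surv_table`.
#' @return Character vector of covariate column names (possibly empty).
#' @export
covariate_names <- function(surv) {
  setdiff(names(surv), c("sample", "time", "status"))
}

#' Construct a signature
#'
#' A signature is an ordered table of features with their aggregated Cox
#' regression coefficients and selection metadata: how many bootstrap
#' iterations sampled the feature and in how many its fitted coefficient was
#' non-zero.
#'
#' @param feature Character feature identifiers (unique).
#' @param coefficient Signed aggregated coefficients.
#' @param times_sampled,times_nonzero Selection counts per feature.
#' @return A data frame of class `cox_signature`.
#' @export
cox_signature <- function(feature, coefficient,
                          times_sampled = rep(1L, length(feature)),
                          times_nonzero = as.integer(coefficient != 0)) {
  feature <- as.character(feature)
  if (anyDuplicated(feature))
    stop("duplicate features in signature: ",
         paste(unique(feature[duplicated(feature)]), collapse = ", "))
  if (any(!is.finite(coefficient)))
    stop("signature coefficients must be finite")
  if (any(times_nonzero > times_sampled))
    stop("times_nonzero cannot exceed times_sampled")
  if (any(times_sampled <= 0))
    stop("features never sampled must be absent from the signature")
  out <- data.frame(feature = feature,
                    coefficient = as.numeric(coefficient),
                    times_sampled = as.integer(times_sampled),
                    times_nonzero = as.integer(times_nonzero),
                    stringsAsFactors = FALSE)
  class(out) <- c("cox_signature", "data.frame")
  out
}

#' @export
print.cox_signature <- function(x, n = 10L, ...) {
  cat("Prognostic signature:", nrow(x), "feature(s)\n")
  print.data.frame(utils::head(as.data.frame(x), n), row.names = FALSE)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more\n")
  invisible(x)
}

#' Read a signature from TSV
#'
#' Expects mandatory columns `feature` and `coefficient`; the metadata
#' columns `times_sampled` and `times_nonzero` are optional.
#'
#' @param path Path to a signature TSV.
#' @return A `cox_signature`.
#' @export
read_signature <- function(path) {
  raw <- read_tsv_table(path)
  if (!all(c("feature", "coefficient") %in% names(raw)))
    stop("signature file needs 'feature' and 'coefficient' columns: ", path)
  coefs <- suppressWarnings(as.numeric(raw$coefficient))
  if (any(is.na(coefs)))
    stop("non-numeric coefficient(s) in ", path)
  ts <- if ("times_sampled" %in% names(raw))
    as.integer(raw$times_sampled) else rep(1L, nrow(raw))
  tn <- if ("times_nonzero" %in% names(raw))
    as.integer(raw$times_nonzero) else as.integer(coefs != 0)
  cox_signature(raw$feature, coefs, ts, tn)
}

#' Write a signature to TSV
#'
#' Coefficients are printed at full double precision so write/read
#' round-trips are lossless.
#'
#' @param sig A `cox_signature`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  df <- as.data.frame(sig)
  df$coefficient <- sprintf("%.17g", df$coefficient)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Join expression and survival data on shared samples
#'
#' Inner join by sample identifier; identifiers present on one side only are
#' dropped with a warning listing them. Row order follows the expression
#' matrix, so permuting either input never changes downstream results.
#'
#' @param expr Samples x features expression matrix.
#' @param surv A `surv_table`.
#' @return List with aligned `expr` and `surv`.
#' @export
join_cohort <- function(expr, surv) {
  expr <- validate_expression(expr)
  shared <- intersect(rownames(expr), surv$sample)
  if (length(shared) == 0L)
    stop("no shared sample identifiers between expression and survival data")
  dropped <- c(setdiff(rownames(expr), shared), setdiff(surv$sample, shared))
  if (length(dropped) > 0L)
    warning("dropping ", length(dropped),
            " sample(s) absent from one input: ",
            paste(utils::head(sort(dropped), 10L), collapse = ", "),
            if (length(dropped) > 10L) ", ..." else "")
  shared <- rownames(expr)[rownames(expr) %in% shared]
  surv2 <- surv[match(shared, surv$sample), , drop = FALSE]
  rownames(surv2) <- NULL
  class(surv2) <- class(surv)
  list(expr = expr[shared, , drop = FALSE], surv = surv2)
}

# -- internal TSV plumbing ---------------------------------------------------

# Minimal strict TSV dialect: tab-delimited, header row, '.' decimals,
# no quoting (identifiers may not contain tabs).
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

as_numeric_grid <- function(raw, path) {
  cn <- names(raw)[-1L]
  if (anyDuplicated(cn))
    stop("duplicate column identifiers in ", path, ": ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "))
  m <- matrix(NA_real_, nrow(raw), length(cn), dimnames = list(NULL, cn))
  for (j in seq_along(cn)) {
    v <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(v))
    if (any(is.na(num) & !is.na(v)))
      stop("non-numeric value in column '", cn[j], "', row ",
           which(is.na(num) & !is.na(v))[1L], " of ", path)
    if (any(is.na(num)))
      stop("missing value in column '", cn[j], "' of ", path)
    m[, j] <- num
  }
  m
}
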