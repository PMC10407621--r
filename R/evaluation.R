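# Fit statistics (R2, MSE, RMSE, MPE) and leverage-based applicability
# domain: hat-matrix leverages, critical leverage, standardized residuals,
# Williams-plot export.

#' Fit statistics for predicted vs experimental responses
#'
#' `r2 = 1 - SS_res / SS_tot` (see `use_pearson` for the squared-correlation
#' alternative), `mse = mean squared error`, `rmse = sqrt(mse)`, and the
#' mean percentage error `mpe = (100/n') sum |y_exp - y_pred| / y_exp` over
#' the `n'` samples with nonzero experimental value (zero-valued targets are
#' excluded; the count is reported).
#'
#' @param y_exp experimental values.
#' @param y_pred predicted values.
#' @param scope label: `"total"`, `"training"`, `"test"`, or `"validation"`.
#' @param use_pearson if `TRUE`, report squared Pearson correlation as `r2`.
#' @return an `ro_fit_metrics`: list with `r2`, `mse`, `rmse`, `mpe`, `n`,
#'   `n_mpe_excluded`, `scope`.
#' @export
fit_metrics <- function(y_exp, y_pred,
                        scope = c("total", "training", "test", "validation"),
                        use_pearson = FALSE) {
  scope <- match.arg(scope)
  stopifnot(length(y_exp) == length(y_pred), length(y_exp) >= 2L)
  if (stats::var(y_exp) == 0) stop("all experimental values identical; R2 undefined")
  res <- y_exp - y_pred
  mse <- mean(res^2)
  r2 <- if (use_pearson) stats::cor(y_exp, y_pred)^2 else
    1 - sum(res^2) / sum((y_exp - mean(y_exp))^2)
  nz <- y_exp != 0
  if (!any(nz)) stop("all experimental values are zero; MPE undefined")
  mpe <- 100 * mean(abs(res[nz]) / abs(y_exp[nz]))
  structure(list(r2 = r2, mse = mse, rmse = sqrt(mse), mpe = mpe,
                 n = length(y_exp), n_mpe_excluded = sum(!nz), scope = scope),
            class = "ro_fit_metrics")
}

#' @export
print.ro_fit_metrics <- function(x, ...) {
  cat(sprintf("<ro_fit_metrics> %s (n=%d): R2=%.4f MSE=%.4f RMSE=%.4f MPE=%.2f%%\n",
              x$scope, x$n, x$r2, x$mse, x$rmse, x$mpe))
  if (x$n_mpe_excluded > 0) {
    cat("  (", x$n_mpe_excluded, "zero-valued target(s) excluded from MPE )\n")
  }
  invisible(x)
}

#' Leverage of query compounds with respect to a training matrix
#'
#' `h_i = x_i (X'X)^{-1} x_i'` with the selected-descriptor matrix used as
#' printed (no intercept column), so training self-leverages sum to the
#' number of descriptors.
#'
#' @param X_train training descriptor matrix (full column rank, rows >=
#'   columns).
#' @param X_query matrix of query rows (default: the training matrix
#'   itself).
#' @return numeric leverage per query row.
#' @export
leverage <- function(X_train, X_query = X_train) {
  X_train <- as.matrix(X_train); X_query <- as.matrix(X_query)
  stopifnot(ncol(X_query) == ncol(X_train))
  if (nrow(X_train) < ncol(X_train)) stop("training matrix has fewer rows than columns")
  XtX <- crossprod(X_train)
  inv <- tryCatch(solve(XtX), error = function(e) {
    stop("X'X is singular; remove collinear descriptors first")
  })
  rowSums((X_query %*% inv) * X_query)
}

#' Critical leverage
#'
#' `h* = 3 (m + 1) / n` for `n` training compounds and `m` descriptors.
#'
#' @param n_train number of training compounds.
#' @param m number of descriptors in the model.
#' @return the critical leverage threshold.
#' @export
critical_leverage <- function(n_train, m) {
  stopifnot(n_train > 0, m >= 0)
  3 * (m + 1) / n_train
}

#' Applicability-domain report (Williams plot data)
#'
#' Standardized residuals (residual divided by the standard deviation of
#' the training residuals) against leverages, with outlier flags: leverage
#' above `h_star` ("leverage"), |standardized residual| > 3 ("residual"),
#' or both.
#'
#' @param y_exp experimental responses for all compounds.
#' @param y_pred model predictions for all compounds.
#' @param X descriptor matrix for all compounds (selected descriptors).
#' @param splits factor of split labels (training/test/validation).
#' @param h_star critical leverage; default computed from the training rows.
#' @param compounds optional compound names.
#' @return an `ro_ad_report`: list with `table` (data frame `compound`,
#'   `split`, `leverage`, `std_residual`, `flag`), `h_star`,
#'   `sd_train_residuals`, `outliers` (names of flagged compounds).
#' @export
williams_report <- function(y_exp, y_pred, X, splits, h_star = NULL,
                            compounds = NULL) {
  X <- as.matrix(X)
  stopifnot(length(y_exp) == nrow(X), length(y_pred) == nrow(X),
            length(splits) == nrow(X))
  tr <- splits == "training"
  if (!any(tr)) stop("no training rows; cannot define the applicability domain")
  res <- y_exp - y_pred
  s <- stats::sd(res[tr])
  if (s == 0) stop("degenerate zero training residual spread")
  if (is.null(h_star)) h_star <- critical_leverage(sum(tr), ncol(X))
  h <- leverage(X[tr, , drop = FALSE], X)
  z <- res / s
  flag <- ifelse(h > h_star & abs(z) > 3, "both",
          ifelse(h > h_star, "leverage",
          ifelse(abs(z) > 3, "residual", "ok")))
  if (is.null(compounds)) compounds <- rownames(X) %||% as.character(seq_len(nrow(X)))
  tab <- data.frame(compound = compounds, split = as.character(splits),
                    leverage = h, std_residual = z, flag = flag,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, h_star = h_star, sd_train_residuals = s,
                 outliers = tab$compound[tab$flag != "ok"]),
            class = "ro_ad_report")
}

#' @export
print.ro_ad_report <- function(x, ...) {
  cat("<ro_ad_report> n =", nrow(x$table), "| h* =", x$h_star,
      "| outliers:", length(x$outliers), "\n")
  if (length(x$outliers)) print(x$table[x$table$flag != "ok", ])
  invisible(x)
}

#' Write Williams-plot data to TSV
#'
#' @param report an `ro_ad_report`.
#' @param path output path.
#' @export
write_williams_tsv <- function(report, path) {
  stopifnot(inherits(report, "ro_ad_report"))
  utils::write.table(report$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
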