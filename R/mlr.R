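# Multiple linear regression baseline and the published reference model.

#' Fit a multiple linear regression model
#'
#' Ordinary least squares via QR decomposition. The fit must be full rank;
#' rank deficiency raises an error naming the aliased columns.
#'
#' @param X numeric descriptor matrix (named columns), rows > columns.
#' @param y response vector.
#' @return an `ro_mlr`: list with `intercept`, `coefficients` (named),
#'   `scale_note` (`"raw"`: applies to unscaled descriptors).
#' @export
fit_mlr <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) <= ncol(X)) stop("OLS needs more rows than descriptor columns")
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  if (fit$rank < ncol(X) + 1L) {
    aliased <- colnames(X)[is.na(fit$coefficients[-1])]
    stop("rank-deficient descriptor matrix; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  cf <- fit$coefficients
  structure(list(intercept = unname(cf[1]),
                 coefficients = cf[-1],
                 scale_note = "raw"),
            class = "ro_mlr")
}

#' Predict with an MLR model
#'
#' Affine evaluation `intercept + X beta`. Columns must match the model's
#' coefficient names (when both are named).
#'
#' @param object an `ro_mlr`.
#' @param newdata descriptor matrix.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.ro_mlr <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  nms <- names(object$coefficients)
  if (!is.null(nms) && !is.null(colnames(X))) {
    if (!all(nms %in% colnames(X))) {
      stop("newdata lacks descriptor column(s): ",
           paste(setdiff(nms, colnames(X)), collapse = ", "))
    }
    X <- X[, nms, drop = FALSE]
  } else if (ncol(X) != length(object$coefficients)) {
    stop("newdata has ", ncol(X), " columns; model expects ",
         length(object$coefficients))
  }
  drop(object$intercept + X %*% object$coefficients)
}

#' The published linear reference model
#'
#' Returns the study's reported MLR equation
#' `y = 0.1632 - 0.1963528 SIC1 + 0.4113547 R2e + 0.1675084 EEig03d +
#' 0.867939 ESpm14u` verbatim. The coefficient magnitudes imply normalized
#' variables, so `scale_note` is `"scaled"`; the model is shipped for
#' reference and sign-pattern interpretation, not for raw-scale prediction.
#'
#' @return an `ro_mlr` with the printed coefficients.
#' @export
eq_reference_mlr <- function() {
  structure(list(intercept = 0.1632,
                 coefficients = c(SIC1 = -0.1963528, R2e = 0.4113547,
                                  EEig03d = 0.1675084, ESpm14u = 0.867939),
                 scale_note = "scaled"),
            class = "ro_mlr")
}

#' @export
print.ro_mlr <- function(x, ...) {
  cat("<ro_mlr> (", x$scale_note, " scale)\n  intercept: ", x$intercept, "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}
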