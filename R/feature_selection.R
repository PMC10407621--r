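# Descriptor filtering cascade: zero-variance removal -> pairwise
# correlation pruning -> forward stepwise p-value ranking -> top-k pick.

#' Remove zero-variance descriptor columns
#'
#' Drops every column whose values are all identical (this includes, but is
#' not limited to, all-zero columns).
#'
#' @param X numeric matrix or data frame of descriptors (named columns).
#' @return list with `X` (reduced matrix) and `removed` (dropped names).
#' @export
drop_zero_variance <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) == 0L || nrow(X) == 0L) stop("descriptor matrix is empty")
  v <- apply(X, 2, stats::var)
  zero <- v == 0 | is.na(v)
  if (all(zero)) stop("all descriptor columns have zero variance; nothing survives")
  list(X = X[, !zero, drop = FALSE], removed = colnames(X)[zero])
}

#' Prune highly correlated descriptor pairs
#'
#' While any pair of columns has `|Pearson r| > threshold`, the member of
#' the worst offending pair with the smaller absolute correlation to the
#' response is dropped (the survivor carries more information about `y`);
#' ties fall to the later column in the current ordering.
#'
#' @param X numeric descriptor matrix (no zero-variance columns; run
#'   [drop_zero_variance()] first).
#' @param y response vector.
#' @param threshold correlation threshold, strict inequality (default 0.90).
#' @return list with `X` (reduced) and `removed` (dropped names, in drop
#'   order).
#' @export
prune_correlated <- function(X, y, threshold = 0.90) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) return(list(X = X, removed = character(0)))
  if (any(apply(X, 2, stats::var) == 0)) {
    stop("zero-variance column present; run drop_zero_variance() first")
  }
  removed <- character(0)
  repeat {
    C <- abs(stats::cor(X))
    diag(C) <- 0
    mx <- max(C)
    if (mx <= threshold) break
    pair <- which(C == mx, arr.ind = TRUE)[1, ]
    ry <- abs(stats::cor(X[, pair], y))
    drop_idx <- pair[if (ry[1] < ry[2]) 1L else 2L]
    removed <- c(removed, colnames(X)[drop_idx])
    X <- X[, -drop_idx, drop = FALSE]
    if (ncol(X) < 2L) break
  }
  list(X = X, removed = removed)
}

# coefficient p-values (t-test = partial F on one added term) of an OLS fit
# of y on the columns of Xsub, named by column; NA for aliased columns
.ro_lm_pvals <- function(Xsub, y) {
  fit <- stats::lm(y ~ Xsub)
  cf <- summary(fit)$coefficients
  beta <- fit$coefficients[-1]  # one per column, in order; NA when aliased
  p <- stats::setNames(rep(NA_real_, ncol(Xsub)), colnames(Xsub))
  ok <- !is.na(beta)
  p[ok] <- cf[-1, 4][seq_len(sum(ok))]
  p
}

#' Forward stepwise regression ranking
#'
#' Forward stepwise linear regression: at each step the candidate descriptor
#' with the smallest partial-F p-value enters if that p-value is below
#' `entry_alpha`; ties break alphabetically for determinism. The final
#' model's coefficient p-values, in ascending order, give the ranking.
#'
#' @param X numeric descriptor matrix.
#' @param y response vector.
#' @param entry_alpha entry threshold (default 0.05).
#' @param ranking `"final_model"` (default: rank by the final joint model's
#'   coefficient p-values) or `"marginal"` (rank by single-descriptor
#'   regression p-values of the entered set).
#' @return an object of class `ro_selection_report`: list with `n_input`,
#'   `n_zero_variance_removed`, `n_correlation_removed`, `stepwise_ranking`
#'   (data frame `descriptor`, `p_value`), `selected` (filled by
#'   [select_top_k()]).
#' @export
stepwise_rank <- function(X, y, entry_alpha = 0.05,
                          ranking = c("final_model", "marginal")) {
  ranking <- match.arg(ranking)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  candidates <- sort(colnames(X))
  entered <- character(0)
  repeat {
    remaining <- setdiff(candidates, entered)
    if (length(remaining) == 0L) break
    if (length(entered) + 2L >= nrow(X)) break  # keep residual df positive
    pvals <- vapply(remaining, function(nm) {
      p <- .ro_lm_pvals(X[, c(entered, nm), drop = FALSE], y)[nm]
      if (is.na(p)) 1 else p  # aliased (collinear) candidate never enters
    }, numeric(1))
    best <- which.min(pvals)  # ties: first in alphabetical candidate order
    if (pvals[best] >= entry_alpha) break
    entered <- c(entered, remaining[best])
  }
  if (length(entered) == 0L) {
    warning("no descriptor passed the entry threshold; empty ranking", call. = FALSE)
    rk <- data.frame(descriptor = character(0), p_value = numeric(0))
  } else if (ranking == "final_model") {
    p <- .ro_lm_pvals(X[, entered, drop = FALSE], y)[entered]
    ord <- order(p, entered)
    rk <- data.frame(descriptor = entered[ord], p_value = unname(p[ord]))
  } else {
    p <- vapply(entered, function(nm) {
      .ro_lm_pvals(X[, nm, drop = FALSE], y)[nm]
    }, numeric(1))
    ord <- order(p, entered)
    rk <- data.frame(descriptor = entered[ord], p_value = unname(p[ord]))
  }
  structure(list(n_input = ncol(X),
                 n_zero_variance_removed = 0L,
                 n_correlation_removed = 0L,
                 stepwise_ranking = rk,
                 selected = character(0)),
            class = "ro_selection_report")
}

#' Take the top-k ranked descriptors
#'
#' @param report an `ro_selection_report` from [stepwise_rank()] or
#'   [select_descriptors()].
#' @param k number of descriptors (default 4).
#' @return the report with `selected` set to the first `k` ranked names.
#' @export
select_top_k <- function(report, k = 4L) {
  stopifnot(inherits(report, "ro_selection_report"), k >= 0L)
  n <- nrow(report$stepwise_ranking)
  if (k > n) {
    stop("ranking has only ", n, " descriptor(s); choose k <= ", n)
  }
  report$selected <- report$stepwise_ranking$descriptor[seq_len(k)]
  report
}

#' Run the full descriptor filtering cascade
#'
#' Zero-variance removal, correlation pruning at `corr_threshold`, forward
#' stepwise ranking, and top-`k` selection, in that order. Deterministic
#' given `X` and `y`.
#'
#' @inheritParams prune_correlated
#' @inheritParams stepwise_rank
#' @inheritParams select_top_k
#' @param corr_threshold pairwise correlation threshold (default 0.90).
#' @return an `ro_selection_report` with all counts filled and the selected
#'   descriptor names.
#' @export
select_descriptors <- function(X, y, k = 4L, corr_threshold = 0.90,
                               entry_alpha = 0.05,
                               ranking = c("final_model", "marginal")) {
  X <- as.matrix(X)
  n_input <- ncol(X)
  zv <- drop_zero_variance(X)
  pc <- prune_correlated(zv$X, y, threshold = corr_threshold)
  report <- stepwise_rank(pc$X, y, entry_alpha = entry_alpha,
                          ranking = match.arg(ranking))
  report$n_input <- n_input
  report$n_zero_variance_removed <- length(zv$removed)
  report$n_correlation_removed <- length(pc$removed)
  report$removed_zero_variance <- zv$removed
  report$removed_correlated <- pc$removed
  select_top_k(report, k = min(k, nrow(report$stepwise_ranking)))
}

#' @export
print.ro_selection_report <- function(x, ...) {
  cat("<ro_selection_report>\n",
      " input descriptors:      ", x$n_input, "\n",
      " zero-variance removed:  ", x$n_zero_variance_removed, "\n",
      " correlation removed:    ", x$n_correlation_removed, "\n", sep = "")
  cat(" stepwise ranking:\n")
  print(x$stepwise_ranking, row.names = FALSE)
  cat(" selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
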