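# Back-propagation feedforward network (n_in - n_hidden - 1, log-sigmoid
# hidden layer, linear output) trained by Levenberg-Marquardt with early
# stopping, plus min-max scaling and Garson connection-weight importance.

logsig <- function(x) 1 / (1 + exp(-x))

#' Min-max scaler
#'
#' Linear map sending the observed `[x_min, x_max]` of each variable to
#' `[r_min, r_max]` (default `[-1, 1]`). Fit the parameters on training data
#' only, then apply them everywhere.
#'
#' @param x numeric matrix (variables in columns) or vector.
#' @param r_min,r_max target range bounds.
#' @return an `ro_scaler`: list with `x_min`, `x_max`, `r_min`, `r_max`.
#' @export
scaler_fit <- function(x, r_min = -1, r_max = 1) {
  stopifnot(r_min < r_max)
  x <- as.matrix(x)
  x_min <- apply(x, 2, min); x_max <- apply(x, 2, max)
  if (any(x_max == x_min)) {
    stop("degenerate variable(s) with x_max == x_min: ",
         paste(colnames(x)[x_max == x_min], collapse = ", "),
         " (zero-variance columns should have been filtered)")
  }
  structure(list(x_min = x_min, x_max = x_max, r_min = r_min, r_max = r_max),
            class = "ro_scaler")
}

#' @rdname scaler_fit
#' @param params an `ro_scaler` from [scaler_fit()].
#' @export
scale_values <- function(x, params) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, params$x_min), 2, params$x_max - params$x_min, "/") *
    (params$r_max - params$r_min) + params$r_min
}

#' @rdname scaler_fit
#' @export
unscale_values <- function(x, params) {
  x <- as.matrix(x)
  sweep(sweep((x - params$r_min) / (params$r_max - params$r_min), 2,
              params$x_max - params$x_min, "*"), 2, params$x_min, "+")
}

#' Network weights container
#'
#' @param W input-to-hidden weight matrix (`n_in` x `n_hidden`; `W[i, j]`
#'   connects input i to hidden node j).
#' @param b_hidden hidden bias vector (`n_hidden`).
#' @param v hidden-to-output weight vector (`n_hidden`).
#' @param b_out output bias scalar.
#' @return an `ro_ann_weights` list.
#' @export
ann_weights <- function(W, b_hidden, v, b_out) {
  W <- as.matrix(W)
  stopifnot(ncol(W) == length(b_hidden), ncol(W) == length(v),
            length(b_out) == 1L, all(is.finite(c(W, b_hidden, v, b_out))))
  structure(list(W = W, b_hidden = as.numeric(b_hidden),
                 v = as.numeric(v), b_out = as.numeric(b_out)),
            class = "ro_ann_weights")
}

#' Forward pass of the network
#'
#' Hidden activations `h = logsig(W'a + b_hidden)`; output `v.h + b_out`
#' (linear output unit). Operates on scaled inputs.
#'
#' @param weights an `ro_ann_weights`.
#' @param inputs numeric vector (one sample) or matrix (samples in rows).
#' @return numeric vector of scaled predictions.
#' @export
ann_forward <- function(weights, inputs) {
  A <- if (is.matrix(inputs)) inputs else matrix(inputs, nrow = 1)
  if (!all(is.finite(A))) stop("non-finite network input rejected")
  if (ncol(A) != nrow(weights$W)) stop("input length does not match topology")
  H <- logsig(sweep(A %*% weights$W, 2, weights$b_hidden, "+"))
  drop(H %*% weights$v + weights$b_out)
}

#' Training configuration
#'
#' Defaults follow the study setup: 4-4-1 topology, log-sigmoid hidden
#' layer, Levenberg-Marquardt training, early stopping after more than 10
#' consecutive validation failures, gradient threshold 1e-7, damping
#' parameter cap 1e10, at most 1000 epochs.
#'
#' @param topology integer vector `(n_in, n_hidden, n_out)`; `n_out` must
#'   be 1.
#' @param algorithm `"levenberg_marquardt"` or `"gradient"` (online delta
#'   rule / backpropagation with learning parameter `eta`).
#' @param eta learning parameter for gradient mode; must stay below 0.1.
#' @param max_validation_failures consecutive epochs without validation
#'   improvement tolerated before stopping.
#' @param min_gradient stop when the MSE gradient norm falls below this.
#' @param max_mu stop when the damping parameter exceeds this.
#' @param max_epochs epoch cap.
#' @param seed integer seed for weight initialization (uniform(-0.5, 0.5)).
#' @param n_restarts number of random initializations tried (derived seeds
#'   `seed, seed + 1, ...`); the restart with the best validation MSE (or
#'   training MSE without a validation split) is kept. Multiple restarts
#'   reduce the chance of a poor local minimum.
#' @return an `ro_train_config` list.
#' @export
ann_config <- function(topology = c(4L, 4L, 1L),
                       algorithm = c("levenberg_marquardt", "gradient"),
                       eta = 0.05,
                       max_validation_failures = 10L,
                       min_gradient = 1e-7,
                       max_mu = 1e10,
                       max_epochs = 1000L,
                       seed = 1L,
                       n_restarts = 5L) {
  algorithm <- match.arg(algorithm)
  stopifnot(length(topology) == 3L, topology[3] == 1L, all(topology >= 1L),
            eta > 0, eta < 0.1, min_gradient > 0, max_mu > 0, max_epochs >= 1L,
            n_restarts >= 1L)
  structure(list(topology = as.integer(topology), algorithm = algorithm,
                 eta = eta, max_validation_failures = as.integer(max_validation_failures),
                 min_gradient = min_gradient, max_mu = max_mu,
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 n_restarts = as.integer(n_restarts)),
            class = "ro_train_config")
}

# pack/unpack parameter vector: [vec(W), b_hidden, v, b_out]
.ro_pack <- function(w) c(as.numeric(w$W), w$b_hidden, w$v, w$b_out)
.ro_unpack <- function(theta, n_in, n_h) {
  W <- matrix(theta[seq_len(n_in * n_h)], n_in, n_h)
  off <- n_in * n_h
  ann_weights(W, theta[off + seq_len(n_h)], theta[off + n_h + seq_len(n_h)],
              theta[off + 2L * n_h + 1L])
}

# residuals e = y - f(theta) and Jacobian de/dtheta for the training block
.ro_resid_jac <- function(theta, A, y, n_in, n_h) {
  w <- .ro_unpack(theta, n_in, n_h)
  H <- logsig(sweep(A %*% w$W, 2, w$b_hidden, "+"))
  out <- drop(H %*% w$v + w$b_out)
  e <- y - out
  S <- H * (1 - H) * matrix(w$v, nrow(A), n_h, byrow = TRUE)  # d out / d preact
  JW <- matrix(0, nrow(A), n_in * n_h)
  for (j in seq_len(n_h)) {
    JW[, (j - 1L) * n_in + seq_len(n_in)] <- -A * S[, j]
  }
  J <- cbind(JW, -S, -H, -1)
  list(e = e, J = J)
}

#' Train the feedforward network
#'
#' Scales descriptors and response to `[-1, 1]` with parameters fitted on
#' the training split only, then minimizes training MSE. In
#' Levenberg-Marquardt mode the update is `(J'J + mu I)^{-1} J'e` with `mu`
#' multiplied by 10 on a failed step and divided by 10 on success; training
#' stops when the validation MSE has not improved for more than
#' `max_validation_failures` consecutive epochs, the MSE gradient norm drops
#' below `min_gradient`, `mu` exceeds `max_mu`, or `max_epochs` is reached.
#' When a validation split is present, the returned weights are those of the
#' best validation epoch. Gradient mode applies the online delta rule with
#' learning parameter `eta`. Fully reproducible given `config$seed`.
#'
#' @param dataset an `ro_qsar_dataset` with training/test/validation splits.
#' @param config an `ro_train_config` from [ann_config()].
#' @return an `ro_ann` object: `weights`, `scaler_x`, `scaler_y`,
#'   `epochs_run`, `stop_reason`, `history` (per-epoch train/validation MSE,
#'   scaled space), `config`.
#' @export
ann_train <- function(dataset, config = ann_config()) {
  stopifnot(inherits(dataset, "ro_qsar_dataset"), inherits(config, "ro_train_config"))
  n_in <- config$topology[1]; n_h <- config$topology[2]
  if (ncol(dataset$X) != n_in) {
    stop("dataset has ", ncol(dataset$X), " descriptors but topology expects ", n_in)
  }
  tr <- dataset$splits == "training"
  va <- dataset$splits == "validation"
  if (!any(tr)) stop("configuration error: dataset has no training split")
  has_val <- any(va)

  scaler_x <- scaler_fit(dataset$X[tr, , drop = FALSE])
  scaler_y <- scaler_fit(matrix(dataset$y[tr], ncol = 1))
  A <- scale_values(dataset$X, scaler_x)
  yS <- drop(scale_values(matrix(dataset$y, ncol = 1), scaler_y))
  Atr <- A[tr, , drop = FALSE]; ytr <- yS[tr]
  Ava <- A[va, , drop = FALSE]; yva <- yS[va]

  mse_of <- function(theta, Ax, yx) {
    w <- .ro_unpack(theta, n_in, n_h)
    mean((yx - ann_forward(w, Ax))^2)
  }

  runs <- lapply(seq_len(config$n_restarts) - 1L, function(offset) {
    .ro_train_once(Atr, ytr, Ava, yva, has_val, config,
                   seed = config$seed + offset, n_in = n_in, n_h = n_h,
                   mse_of = mse_of)
  })
  score <- vapply(runs, function(r) {
    if (has_val) mse_of(r$theta, Ava, yva) else mse_of(r$theta, Atr, ytr)
  }, numeric(1))
  best <- runs[[which.min(score)]]

  structure(list(weights = .ro_unpack(best$theta, n_in, n_h),
                 scaler_x = scaler_x, scaler_y = scaler_y,
                 epochs_run = best$epochs_run, stop_reason = best$stop_reason,
                 history = best$history, config = config,
                 restart_scores = score,
                 descriptor_names = colnames(dataset$X)),
            class = "ro_ann")
}

# one training run from a single random initialization
.ro_train_once <- function(Atr, ytr, Ava, yva, has_val, config, seed,
                           n_in, n_h, mse_of) {
  set.seed(seed)
  n_par <- n_in * n_h + 2L * n_h + 1L
  theta <- stats::runif(n_par, -0.5, 0.5)

  history <- data.frame(epoch = integer(0), mse_train = numeric(0),
                        mse_validation = numeric(0))
  best_val <- Inf; best_theta <- theta; fails <- 0L
  stop_reason <- "max_epochs"; epoch <- 0L
  mu <- 1e-3

  if (config$algorithm == "levenberg_marquardt") {
    rj <- .ro_resid_jac(theta, Atr, ytr, n_in, n_h)
    sse <- sum(rj$e^2)
    while (epoch < config$max_epochs) {
      epoch <- epoch + 1L
      grad <- 2 * crossprod(rj$J, rj$e) / length(ytr)  # d MSE / d theta
      if (sqrt(sum(grad^2)) < config$min_gradient) {
        stop_reason <- "gradient"
        history <- rbind(history, data.frame(epoch = epoch, mse_train = sse / length(ytr),
                                             mse_validation = if (has_val) mse_of(theta, Ava, yva) else NA_real_))
        break
      }
      JtJ <- crossprod(rj$J); Jte <- crossprod(rj$J, rj$e)
      accepted <- FALSE
      while (!accepted) {
        delta <- tryCatch(solve(JtJ + mu * diag(n_par), -Jte),
                          error = function(e) NULL)
        if (!is.null(delta)) {
          cand <- theta + drop(delta)
          rj_new <- .ro_resid_jac(cand, Atr, ytr, n_in, n_h)
          sse_new <- sum(rj_new$e^2)
          if (is.finite(sse_new) && sse_new < sse) {
            theta <- cand; rj <- rj_new; sse <- sse_new
            mu <- mu / 10; accepted <- TRUE
            break
          }
        }
        mu <- mu * 10
        if (mu > config$max_mu) break
      }
      mse_tr <- sse / length(ytr)
      mse_va <- if (has_val) mse_of(theta, Ava, yva) else NA_real_
      history <- rbind(history, data.frame(epoch = epoch, mse_train = mse_tr,
                                           mse_validation = mse_va))
      if (!is.finite(mse_tr)) stop("training diverged: non-finite loss at epoch ", epoch)
      if (!accepted) { stop_reason <- "mu"; break }
      if (has_val) {
        if (mse_va < best_val - 1e-15) { best_val <- mse_va; best_theta <- theta; fails <- 0L }
        else {
          fails <- fails + 1L
          if (fails > config$max_validation_failures) { stop_reason <- "validation"; break }
        }
      }
    }
  } else {
    n_tr <- nrow(Atr)
    while (epoch < config$max_epochs) {
      epoch <- epoch + 1L
      w <- .ro_unpack(theta, n_in, n_h)
      for (s in seq_len(n_tr)) {
        a <- Atr[s, ]
        h <- logsig(drop(crossprod(w$W, a)) + w$b_hidden)
        o <- sum(w$v * h) + w$b_out
        err <- ytr[s] - o
        # delta rule on the output layer; chain rule for the hidden layer
        dh <- err * w$v * h * (1 - h)
        w$v <- w$v + config$eta * err * h
        w$b_out <- w$b_out + config$eta * err
        w$W <- w$W + config$eta * outer(a, dh)
        w$b_hidden <- w$b_hidden + config$eta * dh
      }
      theta <- .ro_pack(w)
      rj <- .ro_resid_jac(theta, Atr, ytr, n_in, n_h)
      mse_tr <- mean(rj$e^2)
      if (!is.finite(mse_tr)) stop("training diverged: non-finite loss at epoch ", epoch)
      mse_va <- if (has_val) mse_of(theta, Ava, yva) else NA_real_
      history <- rbind(history, data.frame(epoch = epoch, mse_train = mse_tr,
                                           mse_validation = mse_va))
      grad <- 2 * crossprod(rj$J, rj$e) / length(ytr)
      if (sqrt(sum(grad^2)) < config$min_gradient) { stop_reason <- "gradient"; break }
      if (has_val) {
        if (mse_va < best_val - 1e-15) { best_val <- mse_va; best_theta <- theta; fails <- 0L }
        else {
          fails <- fails + 1L
          if (fails > config$max_validation_failures) { stop_reason <- "validation"; break }
        }
      }
    }
  }

  final_theta <- if (has_val && is.finite(best_val) &&
                     best_val <= mse_of(theta, Ava, yva)) best_theta else theta
  list(theta = final_theta, epochs_run = epoch, stop_reason = stop_reason,
       history = history)
}

#' Predict rejections with a trained network
#'
#' @param object an `ro_ann` from [ann_train()].
#' @param newdata descriptor matrix on the raw (unscaled) scale, columns
#'   matching the training descriptors.
#' @param ... unused.
#' @return numeric vector of predictions on the response scale (percent).
#' @export
predict.ro_ann <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$descriptor_names) && !is.null(colnames(X))) {
    if (!all(object$descriptor_names %in% colnames(X))) {
      stop("newdata lacks descriptor column(s): ",
           paste(setdiff(object$descriptor_names, colnames(X)), collapse = ", "))
    }
    X <- X[, object$descriptor_names, drop = FALSE]
  }
  A <- scale_values(X, object$scaler_x)
  out <- ann_forward(object$weights, A)
  drop(unscale_values(matrix(out, ncol = 1), object$scaler_y))
}

#' @export
print.ro_ann <- function(x, ...) {
  cat("<ro_ann> topology", paste(x$config$topology, collapse = "-"),
      "| epochs:", x$epochs_run, "| stop:", x$stop_reason, "\n")
  invisible(x)
}

#' Garson connection-weight importance
#'
#' For input `t`, `Q_t = sum_n (|w_tn| / sum_k |w_kn|) * |v_n|`; the
#' importances are `100 Q_t / sum_t Q_t` and sum to 100. Biases are ignored.
#' A hidden unit whose input weights are all zero contributes nothing.
#'
#' @param weights an `ro_ann_weights` or a trained `ro_ann`.
#' @return named numeric vector of percentages summing to 100.
#' @export
garson_importance <- function(weights) {
  if (inherits(weights, "ro_ann")) {
    nms <- weights$descriptor_names
    weights <- weights$weights
  } else nms <- rownames(weights$W)
  stopifnot(inherits(weights, "ro_ann_weights"))
  aW <- abs(weights$W); av <- abs(weights$v)
  colsum <- colSums(aW)
  contrib <- sweep(aW, 2, ifelse(colsum == 0, 1, colsum), "/")
  contrib[, colsum == 0] <- 0
  Q <- drop(contrib %*% av)
  if (sum(Q) == 0) stop("all connection weights are zero; importance undefined")
  imp <- 100 * Q / sum(Q)
  names(imp) <- nms %||% paste0("input", seq_along(imp))
  imp
}

#' Effective weight table
#'
#' One row per hidden neuron holding its input weights and hidden-to-output
#' weight, plus a final relative-importance row (percent, from
#' [garson_importance()]).
#'
#' @param result a trained `ro_ann` or an `ro_ann_weights`.
#' @param input_names optional descriptor names for the columns.
#' @return data frame; rows `H1..Hn` then `importance`.
#' @export
effective_weight_table <- function(result, input_names = NULL) {
  w <- if (inherits(result, "ro_ann")) result$weights else result
  stopifnot(inherits(w, "ro_ann_weights"))
  if (is.null(input_names)) {
    input_names <- if (inherits(result, "ro_ann")) result$descriptor_names else NULL
  }
  n_in <- nrow(w$W); n_h <- ncol(w$W)
  if (is.null(input_names)) input_names <- paste0("input", seq_len(n_in))
  tab <- as.data.frame(t(w$W))
  names(tab) <- input_names
  tab$hidden_to_out <- w$v
  imp <- garson_importance(if (inherits(result, "ro_ann")) result else w)
  tab <- rbind(tab, c(as.numeric(imp), NA_real_))
  rownames(tab) <- c(paste0("H", seq_len(n_h)), "importance")
  tab
}
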