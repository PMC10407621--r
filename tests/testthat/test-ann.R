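logsig_ <- function(x) 1 / (1 + exp(-x))

make_synth_dataset <- function(n = 200, noise_sd = 3, seed = 11,
                               kind = "hidden_network", informative_only = TRUE) {
  g <- synth_generate(synthetic_spec(n_compounds = n, response_kind = kind,
                                     noise_sd = noise_sd, seed = seed))
  ds <- g$dataset
  if (informative_only) ds$X <- ds$X[, g$truth$informative_names, drop = FALSE]
  list(ds = ds, truth = g$truth)
}

test_that("min-max scaling maps endpoints, midpoint, and round trips", {
  x <- matrix(c(0, 5, 10, 2, 4, 6), ncol = 2)
  colnames(x) <- c("a", "b")
  sc <- scaler_fit(x)
  s <- scale_values(x, sc)
  expect_equal(s[1, ], c(a = -1, b = -1))
  expect_equal(s[3, ], c(a = 1, b = 1))
  expect_equal(unname(s[2, 1]), 0)  # midpoint
  set.seed(1)
  r <- matrix(runif(200, -3, 20), ncol = 2)
  expect_lt(max(abs(unscale_values(scale_values(r, sc), sc) - r)), 1e-12)
  expect_error(scaler_fit(cbind(ok = 1:3, bad = c(2, 2, 2))), "degenerate")
})

test_that("forward pass matches hand calculations", {
  w0 <- ann_weights(matrix(0, 2, 2), c(0, 0), c(0, 0), 0)
  expect_equal(ann_forward(w0, c(0, 0)), 0)  # hidden all logsig(0)=0.5, v=0

  w1 <- ann_weights(matrix(1, 1, 1), 0, 2, 0)
  expect_equal(ann_forward(w1, 0), 1)        # 2*logsig(0)

  # 2-2-1 with weights +-1: independent hand evaluation
  W <- matrix(c(1, -1, -1, 1), 2, 2)
  w2 <- ann_weights(W, c(1, -1), c(1, -1), 0.5)
  a <- c(0.3, -0.7)
  h_hand <- logsig_(drop(crossprod(W, a)) + c(1, -1))
  out_hand <- sum(c(1, -1) * h_hand) + 0.5
  expect_equal(ann_forward(w2, a), out_hand, tolerance = 1e-12)

  expect_error(ann_forward(w2, c(1, NaN)), "non-finite")
  expect_error(ann_forward(w2, c(1, 2, 3)), "topology")
})

test_that("LM training recovers a noiseless hidden-network response", {
  made <- make_synth_dataset(n = 200, noise_sd = 0, seed = 1)
  fit <- ann_train(made$ds, ann_config(seed = 1, n_restarts = 10L))
  te <- made$ds$splits == "test"
  pred <- predict(fit, made$ds$X)
  expect_gte(fit_metrics(made$ds$y[te], pred[te])$r2, 0.99)
  expect_lte(fit$epochs_run, 1000L)
})

test_that("the network subsumes a linear map", {
  set.seed(2)
  X <- matrix(rnorm(240 * 4), 240, 4, dimnames = list(NULL, paste0("D", 1:4)))
  y <- 30 + 20 * X[, 1]
  sizes <- c(168, 36, 36)
  ds <- structure(list(X = X, y = y,
                       splits = factor(rep(c("training", "test", "validation"), sizes)),
                       censored = rep(FALSE, 240), response = "synthetic", meta = list()),
                  class = "ro_qsar_dataset")
  fit <- ann_train(ds, ann_config(seed = 1))
  expect_gte(fit_metrics(y, predict(fit, X))$r2, 0.999)
})

test_that("pure-noise responses stop via the validation rule", {
  stops <- vapply(1:20, function(seed) {
    set.seed(seed + 300)
    X <- matrix(rnorm(80 * 4), 80, 4, dimnames = list(NULL, paste0("D", 1:4)))
    y <- rnorm(80, 50, 10)
    ds <- structure(list(X = X, y = y,
                         splits = factor(rep(c("training", "test", "validation"), c(56, 12, 12))),
                         censored = rep(FALSE, 80), response = "synthetic", meta = list()),
                    class = "ro_qsar_dataset")
    ann_train(ds, ann_config(seed = seed))$stop_reason
  }, character(1))
  expect_gte(mean(stops == "validation"), 0.80)
})

test_that("LM training MSE is non-increasing across accepted steps", {
  made <- make_synth_dataset(n = 120, noise_sd = 3, seed = 9)
  fit <- ann_train(made$ds, ann_config(seed = 9))
  expect_true(all(diff(fit$history$mse_train) <= 1e-12))
})

test_that("training is bit-reproducible given the seed", {
  made <- make_synth_dataset(n = 100, noise_sd = 3, seed = 4)
  f1 <- ann_train(made$ds, ann_config(seed = 21))
  f2 <- ann_train(made$ds, ann_config(seed = 21))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
  f3 <- ann_train(made$ds, ann_config(seed = 22))
  expect_false(identical(f1$weights, f3$weights))
})

test_that("gradient-mode output-layer update equals eta*(t - o)*h by hand", {
  # two training samples so scaling is well-defined; check the first update
  X <- matrix(c(1, 3, 2, 6), 2, 2, dimnames = list(NULL, c("a", "b")))
  y <- c(10, 30)
  ds <- structure(list(X = X, y = y,
                       splits = factor(c("training", "training"),
                                       levels = c("training", "test", "validation")),
                       censored = c(FALSE, FALSE), response = "synthetic", meta = list()),
                  class = "ro_qsar_dataset")
  n_h <- 3L
  cfg <- ann_config(topology = c(2L, n_h, 1L), algorithm = "gradient",
                    eta = 0.05, max_epochs = 1L, seed = 13, n_restarts = 1L)
  fit <- ann_train(ds, cfg)

  set.seed(13)
  theta <- runif(2 * n_h + 2 * n_h + 1, -0.5, 0.5)
  W <- matrix(theta[seq_len(2 * n_h)], 2, n_h)
  bh <- theta[2 * n_h + seq_len(n_h)]
  v <- theta[3 * n_h + seq_len(n_h)]
  bo <- theta[4 * n_h + 1]
  A <- cbind(a = c(-1, 1), b = c(-1, 1))  # scaled inputs
  yS <- c(-1, 1)                          # scaled targets
  for (s in 1:2) {
    h <- logsig_(drop(crossprod(W, A[s, ])) + bh)
    o <- sum(v * h) + bo
    err <- yS[s] - o
    dh <- err * v * h * (1 - h)
    v <- v + 0.05 * err * h          # delta rule: eta * (t - o) * input
    bo <- bo + 0.05 * err
    W <- W + 0.05 * outer(A[s, ], dh)
    bh <- bh + 0.05 * dh
  }
  expect_equal(unname(fit$weights$v), unname(v), tolerance = 1e-12)
  expect_equal(fit$weights$b_out, bo, tolerance = 1e-12)
  expect_equal(unname(fit$weights$W), unname(W), tolerance = 1e-12)
})

test_that("garson importance: symmetry, zero-input, oracle, invariances", {
  # all |weights| equal over 2 inputs -> 50/50
  w <- ann_weights(matrix(c(1, -1, -1, 1), 2, 2), c(0, 0), c(0.5, -0.5), 0)
  expect_equal(unname(garson_importance(w)), c(50, 50))

  # an input with all-zero weights gets 0%
  w0 <- ann_weights(rbind(c(1, 2), c(0, 0)), c(0, 0), c(1, 1), 0)
  expect_equal(unname(garson_importance(w0))[2], 0)

  # brute-force oracle on random weights
  oracle <- function(W, v) {
    Q <- numeric(nrow(W))
    for (t in seq_len(nrow(W))) {
      for (n in seq_len(ncol(W))) {
        denom <- sum(abs(W[, n]))
        if (denom > 0) Q[t] <- Q[t] + abs(W[t, n]) / denom * abs(v[n])
      }
    }
    100 * Q / sum(Q)
  }
  for (seed in 1:10) {
    set.seed(seed)
    W <- matrix(rnorm(4 * 4), 4, 4); v <- rnorm(4)
    got <- garson_importance(ann_weights(W, rnorm(4), v, rnorm(1)))
    expect_equal(unname(got), oracle(W, v), tolerance = 1e-10)
    expect_equal(sum(got), 100, tolerance = 1e-10)
    # invariance: rescaling |v| by a positive constant
    got2 <- garson_importance(ann_weights(W, rnorm(4), v * 3.7, rnorm(1)))
    expect_equal(unname(got2), unname(got), tolerance = 1e-10)
    # invariance: hidden-unit permutation
    perm <- sample(4)
    got3 <- garson_importance(ann_weights(W[, perm], rnorm(4), v[perm], 0))
    expect_equal(unname(got3), unname(got), tolerance = 1e-10)
  }

  # a hidden unit with all-zero input weights contributes nothing
  Wz <- cbind(c(1, 2), c(0, 0))
  wz <- ann_weights(Wz, c(0, 0), c(1, 5), 0)
  expect_equal(unname(garson_importance(wz)), oracle(Wz, c(1, 5)), tolerance = 1e-12)
})

test_that("effective weight table mirrors supplied weights and round trips", {
  W <- matrix(c(-1.0877, 1.8117, 3.6353, 2.2321,
                1.3881, -1.3380, -0.7606, -2.9344,
                0.0052, -1.8139, -1.5711, 2.5124,
                0.9426, -2.1147, 3.9892, 3.6544), 4, 4, byrow = TRUE)
  # W rows above are hidden neurons; the container wants inputs x hidden
  w <- ann_weights(t(W), rep(0, 4), c(0.7219, -0.2206, 0.1505, 0.5867), 0)
  tab <- effective_weight_table(w, input_names = c("SIC1", "R2e", "EEig03d", "ESpm14u"))
  expect_equal(nrow(tab), 5L)
  expect_equal(unname(unlist(tab["H1", 1:4])), W[1, ])
  expect_equal(tab["H3", "hidden_to_out"], 0.1505)
  imp <- unlist(tab["importance", 1:4])
  expect_equal(sum(imp), 100, tolerance = 1e-9)

  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, path)
  back <- utils::read.csv(path, row.names = 1)
  expect_equal(as.matrix(back), as.matrix(tab), tolerance = 1e-12)
})

test_that("train validates inputs", {
  made <- make_synth_dataset(n = 50, seed = 3)
  bad <- made$ds
  bad$splits <- factor(rep("test", 50), levels = c("training", "test", "validation"))
  expect_error(ann_train(bad, ann_config(seed = 1)), "no training split")
  expect_error(ann_train(made$ds, ann_config(topology = c(7L, 4L, 1L), seed = 1)),
               "topology expects")
  expect_error(ann_config(eta = 0.5), "eta")
})
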