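# Synthetic QSAR-like data with known ground truth: a descriptor matrix
# carrying planted zero-variance columns, near-duplicate pairs and four
# informative descriptors, and a bounded percent response (linear or
# hidden-network mechanism) with additive noise.

#' Specification for a synthetic QSAR dataset
#'
#' Defaults mirror the packaged study's shape: 72 compounds split
#' 69.44/15.27/15.27 into training/test/validation, four informative
#' descriptors, a bounded (0-100) response. The extra structure (7 noise
#' columns, 5 zero-variance columns, 3 near-duplicate pairs, noise sd 5
#' percentage points) emulates what a real descriptor block feeds the
#' filtering cascade.
#'
#' @param n_compounds number of rows.
#' @param n_informative informative descriptors (the generator mechanism
#'   uses exactly these; default 4).
#' @param n_noise irrelevant random descriptors.
#' @param n_zero_variance constant columns.
#' @param n_duplicate_pairs columns duplicated (with small jitter, |r| >
#'   0.95) from existing ones.
#' @param response_kind `"hidden_network"` (4-4-1 logistic network mapped to
#'   0-100) or `"linear"`.
#' @param noise_sd additive response noise, percentage points.
#' @param split_fractions training/test/validation fractions.
#' @param seed integer seed.
#' @return an `ro_synth_spec` list.
#' @export
synthetic_spec <- function(n_compounds = 72L, n_informative = 4L,
                           n_noise = 7L, n_zero_variance = 5L,
                           n_duplicate_pairs = 3L,
                           response_kind = c("hidden_network", "linear"),
                           noise_sd = 5,
                           split_fractions = c(0.6944, 0.1527, 0.1527),
                           seed = 1L) {
  response_kind <- match.arg(response_kind)
  stopifnot(n_compounds >= 0L, n_informative >= 1L, n_noise >= 0L,
            n_zero_variance >= 0L, n_duplicate_pairs >= 0L, noise_sd >= 0,
            length(split_fractions) == 3L,
            abs(sum(split_fractions) - 1) < 1e-2)
  structure(list(n_compounds = as.integer(n_compounds),
                 n_informative = as.integer(n_informative),
                 n_noise = as.integer(n_noise),
                 n_zero_variance = as.integer(n_zero_variance),
                 n_duplicate_pairs = as.integer(n_duplicate_pairs),
                 response_kind = response_kind, noise_sd = noise_sd,
                 split_fractions = split_fractions, seed = as.integer(seed)),
            class = "ro_synth_spec")
}

# largest-remainder apportionment of n rows to the three split fractions
.ro_split_sizes <- function(n, fractions) {
  raw <- n * fractions / sum(fractions)
  sizes <- floor(raw)
  left <- n - sum(sizes)
  if (left > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(left)]
    sizes[extra] <- sizes[extra] + 1
  }
  as.integer(sizes)
}

#' Generate a synthetic QSAR dataset with ground truth
#'
#' Informative and noise descriptors are drawn from a Gaussian factor model
#' (three latent factors, loading 0.4) so columns carry mild realistic
#' correlation; duplicate columns are copies plus N(0, 0.05) jitter
#' (|r| > 0.95 by construction); zero-variance columns are constants. The
#' response is `y = 50 + X beta + eps` (linear; `beta = (12, -8, 10, 6)`
#' recycled) or `y = 100 logsig(z) + eps` with `z` the standardized output
#' of a seeded 4-4-1 log-sigmoid network over the informative block
#' (hidden-network). Responses are clipped to [0, 100]; the clip rate is
#' recorded and kept small by the scaling of `z`.
#'
#' @param spec an `ro_synth_spec`.
#' @param loadings optional factor-loading matrix reused from a previous
#'   draw (as stored in the ground truth; used by [synth_regenerate()]).
#' @return list with `dataset` (an `ro_qsar_dataset`) and `truth` (an
#'   `ro_ground_truth`: informative names, generator weights or
#'   coefficients, noise sd, the spec, clip rate).
#' @export
synth_generate <- function(spec, loadings = NULL) {
  stopifnot(inherits(spec, "ro_synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_compounds
  p_base <- spec$n_informative + spec$n_noise
  if (n > 0 && n < 3L && any(spec$split_fractions > 0)) {
    stop("n_compounds too small to populate the three splits")
  }

  # factor model: each column loads with norm 0.4 on 3 latent factors, so
  # columns are unit-variance with mild mutual correlation; the loadings are
  # part of the mechanism and are reused by synth_regenerate()
  q <- 3L
  if (is.null(loadings)) {
    lam <- matrix(stats::runif(p_base * q, -1, 1), p_base, q)
    lam <- 0.4 * lam / pmax(sqrt(rowSums(lam^2)), 1e-12)
  } else {
    lam <- loadings
    stopifnot(nrow(lam) == p_base, ncol(lam) == q)
  }
  L <- matrix(stats::rnorm(n * q), n, q)
  X <- L %*% t(lam) + matrix(stats::rnorm(n * p_base), n, p_base) * sqrt(1 - 0.4^2)
  inf_names <- paste0("D_inf", seq_len(spec$n_informative))
  noise_names <- if (spec$n_noise > 0) paste0("D_noise", seq_len(spec$n_noise)) else character(0)
  colnames(X) <- c(inf_names, noise_names)

  # planted duplicates: copy + jitter; a duplicate of an informative column
  # carries the same signal, so an alias map is kept for recovery checks
  aliases <- character(0)
  if (spec$n_duplicate_pairs > 0) {
    src <- rep(seq_len(p_base), length.out = spec$n_duplicate_pairs)
    dup <- vapply(src, function(s) X[, s] + stats::rnorm(n, sd = 0.05),
                  numeric(n))
    dup <- matrix(dup, nrow = n, ncol = length(src))
    colnames(dup) <- paste0("D_dup", seq_len(spec$n_duplicate_pairs),
                            "_of_", colnames(X)[src])
    aliases <- stats::setNames(colnames(X)[src], colnames(dup))
    X <- cbind(X, dup)
  }
  # planted constants (half zero, half nonzero constants)
  if (spec$n_zero_variance > 0) {
    zv <- vapply(seq_len(spec$n_zero_variance),
                 function(k) rep(if (k %% 2 == 0) 0 else k, n), numeric(n))
    zv <- matrix(zv, nrow = n, ncol = spec$n_zero_variance)
    colnames(zv) <- paste0("D_const", seq_len(spec$n_zero_variance))
    X <- cbind(X, zv)
  }

  Xinf <- X[, inf_names, drop = FALSE]
  if (spec$response_kind == "linear") {
    beta <- rep(c(12, -8, 10, 6), length.out = spec$n_informative)
    signal <- 50 + drop(Xinf %*% beta)
    gen <- list(beta = stats::setNames(beta, inf_names), intercept = 50)
  } else {
    n_h <- 4L
    W <- matrix(stats::runif(spec$n_informative * n_h, -2.5, 2.5),
                spec$n_informative, n_h)
    b_h <- stats::runif(n_h, -1, 1)
    v <- stats::runif(n_h, -2, 2)
    b_o <- stats::runif(1, -0.5, 0.5)
    w <- ann_weights(W, b_h, v, b_o)
    z <- ann_forward(w, Xinf)
    # standardize the raw network output to sd 1.5 so the logistic response
    # spans the percent scale like real rejection data while keeping the
    # clipping rate near 2%
    zs <- if (n > 1 && stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) * 1.5 else z * 0
    signal <- 100 * logsig(zs)
    gen <- list(weights = w, output_standardization = "sd 1.5")
  }
  y_raw <- signal + stats::rnorm(n, sd = spec$noise_sd)
  y <- pmin(100, pmax(0, y_raw))
  clip_rate <- if (n > 0) mean(y_raw != y) else 0

  sizes <- .ro_split_sizes(n, spec$split_fractions)
  splits <- factor(rep(c("training", "test", "validation"), times = sizes),
                   levels = c("training", "test", "validation"))
  if (n > 0) splits <- splits[sample.int(n)]  # seeded permutation
  rownames(X) <- if (n > 0) sprintf("synth%03d", seq_len(n)) else NULL

  dataset <- structure(list(X = X, y = y, splits = splits,
                            censored = rep(FALSE, n), response = "synthetic",
                            meta = list(generator = spec$response_kind)),
                       class = "ro_qsar_dataset")
  truth <- structure(list(informative_names = inf_names, aliases = aliases,
                          generator = gen, loadings = lam,
                          noise_sd = spec$noise_sd,
                          spec = spec, clip_rate = clip_rate),
                     class = "ro_ground_truth")
  list(dataset = dataset, truth = truth)
}

#' Resolve descriptor names through the ground-truth alias map
#'
#' Maps planted duplicate column names back to their source columns, so
#' recovery checks can credit a selected duplicate of an informative
#' descriptor.
#'
#' @param names character vector of descriptor names.
#' @param truth an `ro_ground_truth`.
#' @return character vector with duplicates replaced by their sources.
#' @export
resolve_aliases <- function(names, truth) {
  stopifnot(inherits(truth, "ro_ground_truth"))
  hit <- names %in% names(truth$aliases)
  names[hit] <- truth$aliases[names[hit]]
  names
}

#' Regenerate a dataset from stored ground truth
#'
#' Draws a fresh dataset of `n` rows from the same mechanism (same
#' informative structure and generator weights) under a seed derived from
#' the original: `seed + 7919 * draw`.
#'
#' @param truth an `ro_ground_truth` from [synth_generate()].
#' @param n number of rows (default: as in the original spec).
#' @param draw index of the fresh draw (default 1).
#' @return list with `dataset` and `truth`, as [synth_generate()].
#' @export
synth_regenerate <- function(truth, n = NULL, draw = 1L) {
  stopifnot(inherits(truth, "ro_ground_truth"))
  spec <- truth$spec
  if (!is.null(n)) spec$n_compounds <- as.integer(n)
  spec$seed <- as.integer((spec$seed + 7919L * as.integer(draw)) %% .Machine$integer.max)
  out <- synth_generate(spec, loadings = truth$loadings)
  # regeneration keeps the original mechanism parameters
  out$truth$generator <- truth$generator
  out$truth$loadings <- truth$loadings
  if (spec$n_compounds > 0) {
    Xinf <- out$dataset$X[, truth$informative_names, drop = FALSE]
    gen <- truth$generator
    signal <- if (!is.null(gen$beta)) {
      gen$intercept + drop(Xinf %*% gen$beta)
    } else {
      z <- ann_forward(gen$weights, Xinf)
      zs <- if (nrow(Xinf) > 1 && stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) * 2 else z * 0
      100 * logsig(zs)
    }
    y_raw <- signal + stats::rnorm(spec$n_compounds, sd = truth$noise_sd)
    out$dataset$y <- pmin(100, pmax(0, y_raw))
  }
  out
}
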