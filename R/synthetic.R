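# Synthetic Granger-structured benchmark generator: sparse stationary VAR(1)
# processes (linear or tanh-linked) with a known directed causal graph,
# plus block missingness and the train/test benchmark bundle.

# Draw the sparse parent structure and coefficients shared by the linear and
# nonlinear simulators. Returns the (d x d) coefficient matrix C with
# C[i, j] = effect of attribute i at lag 1 on attribute j, and the binary
# true adjacency (i -> j).
var_structure <- function(d, parents_per_node, coef_scale, self_lag, seed) {
  if (d < 2) stop("`d` must be at least 2", call. = FALSE)
  if (parents_per_node < 1 || parents_per_node >= d) {
    stop("`parents_per_node` must lie in [1, d)", call. = FALSE)
  }
  with_seed(seed, {
    coef <- matrix(0, d, d)
    truth <- matrix(0L, d, d)
    for (j in seq_len(d)) {
      parents <- sample(setdiff(seq_len(d), j), parents_per_node)
      truth[parents, j] <- 1L
      signs <- sample(c(-1, 1), parents_per_node, replace = TRUE)
      coef[parents, j] <- signs * stats::runif(parents_per_node, 0.5, 1) *
        coef_scale
      if (self_lag) coef[j, j] <- stats::runif(1, 0.5, 1) * coef_scale
    }
    list(coef = coef, truth = truth)
  })
}

# Rescale a coefficient matrix to a target spectral radius (stationarity).
rescale_spectral <- function(coef, target = 0.9) {
  rho <- max(Mod(eigen(coef, only.values = TRUE)$values))
  if (rho > 0) coef * (target / rho) else coef
}

#' Simulate a sparse stationary VAR(1) with known causal graph
#'
#' Generates an order-1 linear vector autoregression in which each attribute
#' has exactly `parents_per_node` randomly chosen parents (other attributes)
#' plus, optionally, a self-lag. The full coefficient matrix is rescaled to
#' spectral radius 0.9 so the process is stationary but strongly
#' autocorrelated; Gaussian innovations of standard deviation `noise_sd` are
#' added and a 200-step burn-in is discarded. The generated series is fully
#' observed; use [inject_missing()] or [inject_blocks()] to corrupt it.
#'
#' @param d number of attributes (at least 2).
#' @param n number of timestamps kept after burn-in (at least 10).
#' @param parents_per_node number of cross-attribute parents per node.
#' @param coef_scale scale of the raw coefficients before spectral rescaling.
#' @param noise_sd innovation standard deviation.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @param self_lag include a self-lag coefficient per attribute
#'   (default `TRUE`).
#' @return A list of class `synthetic_dataset` with elements `dataset`
#'   (a fully observed [ts_dataset()]), `true_adjacency` (binary `d x d`,
#'   entry `(i, j)` = edge from attribute i to attribute j), `coef` (the
#'   rescaled coefficient matrix) and the generator parameters.
#' @examples
#' sim <- simulate_var(d = 3, n = 50, parents_per_node = 1, seed = 1)
#' sim$true_adjacency
#' @export
simulate_var <- function(d, n, parents_per_node = 2, coef_scale = 0.5,
                         noise_sd = 0.3, seed = 1, self_lag = TRUE) {
  simulate_process(d, n, parents_per_node, coef_scale, noise_sd, seed,
                   self_lag, link = "linear")
}

#' Simulate a sparse VAR(1) with a tanh link
#'
#' Identical sparsity structure and scaling to [simulate_var()], but the
#' parent contribution passes through `tanh` before the innovation is added,
#' giving bounded nonlinear dependencies.
#'
#' @inheritParams simulate_var
#' @return As [simulate_var()].
#' @export
simulate_nonlinear <- function(d, n, parents_per_node = 2, coef_scale = 0.5,
                               noise_sd = 0.3, seed = 1, self_lag = TRUE) {
  simulate_process(d, n, parents_per_node, coef_scale, noise_sd, seed,
                   self_lag, link = "tanh")
}

simulate_process <- function(d, n, parents_per_node, coef_scale, noise_sd,
                             seed, self_lag, link) {
  if (n < 10) stop("`n` must be at least 10", call. = FALSE)
  seeds <- derive_seeds(seed, 2)
  st <- var_structure(d, parents_per_node, coef_scale, self_lag, seeds[1])
  coef <- rescale_spectral(st$coef, 0.9)
  burn <- 200L
  total <- n + burn
  x <- matrix(0, total, d)
  innov <- with_seed(seeds[2], matrix(stats::rnorm(total * d, sd = noise_sd),
                                      total, d))
  x[1, ] <- innov[1, ]
  for (t in 2:total) {
    drive <- drop(x[t - 1L, ] %*% coef)
    if (link == "tanh") drive <- tanh(drive)
    x[t, ] <- drive + innov[t, ]
  }
  vals <- x[(burn + 1L):total, , drop = FALSE]
  colnames(vals) <- paste0("V", seq_len(d))
  structure(
    list(
      dataset = ts_dataset(vals),
      true_adjacency = st$truth,
      coef = coef,
      params = list(
        d = d, n = n, parents_per_node = parents_per_node,
        coef_scale = coef_scale, noise_sd = noise_sd, seed = seed,
        self_lag = self_lag, link = link
      )
    ),
    class = "synthetic_dataset"
  )
}

#' Inject contiguous missing blocks
#'
#' Removes contiguous runs of `block_length` timestamps per attribute at
#' random starting points until approximately `block_rate` of the observed
#' entries have been dropped, emulating sensor outages rather than isolated
#' point losses.
#'
#' @param ds a [ts_dataset()].
#' @param block_length run length of each outage (at least 1, at most `n`).
#' @param block_rate target fraction of observed entries to drop, in `[0, 1)`.
#' @param seed integer seed.
#' @return A list with `corrupted` and `eval_mask`, as [inject_missing()].
#' @export
inject_blocks <- function(ds, block_length, block_rate, seed) {
  stopifnot(inherits(ds, "ts_dataset"))
  n <- nrow(ds$values)
  d <- ncol(ds$values)
  if (block_length < 1 || block_length > n) {
    stop("`block_length` must lie in [1, n]", call. = FALSE)
  }
  if (block_rate < 0 || block_rate >= 1) {
    stop("`block_rate` must lie in [0, 1)", call. = FALSE)
  }
  target <- round(block_rate * sum(ds$mask))
  eval_mask <- matrix(0L, n, d, dimnames = dimnames(ds$mask))
  if (target > 0L) {
    with_seed(seed, {
      guard <- 0L
      while (sum(eval_mask[ds$mask == 1L]) < target && guard < 100000L) {
        j <- sample.int(d, 1L)
        s <- sample.int(n - block_length + 1L, 1L)
        e <- s + block_length - 1L
        # refuse placements that touch an existing block, so no dropped run
        # ever exceeds block_length
        lo <- max(1L, s - 1L)
        hi <- min(n, e + 1L)
        if (all(eval_mask[lo:hi, j] == 0L)) {
          eval_mask[s:e, j] <- 1L
        }
        guard <- guard + 1L
      }
    })
    # only entries that were observed can be evaluated
    eval_mask[ds$mask == 0L] <- 0L
  }
  vals <- ds$values
  vals[eval_mask == 1L] <- NA_real_
  list(
    corrupted = ts_dataset(vals, ds$timestamps, ds$attribute_names),
    eval_mask = eval_mask
  )
}

#' Build a train/test imputation benchmark
#'
#' Splits a synthetic series chronologically into 80% train / 20% test,
#' drops 10% of the training observations (the training protocol) and
#' `p_test` of the test observations, and retains the fully observed ground
#' truth for scoring.
#'
#' @param sim a [simulate_var()] / [simulate_nonlinear()] result, or a fully
#'   observed [ts_dataset()].
#' @param p_test test drop fraction in `(0, 1)`.
#' @param seed integer seed driving both corruption draws.
#' @param p_train training drop fraction (default 0.1).
#' @param train_frac chronological training fraction (default 0.8).
#' @return A list of class `imputation_benchmark` with `train`, `test`
#'   (each holding `truth`, `corrupted`, `eval_mask`), `true_adjacency`
#'   (if available) and the configuration.
#' @export
make_benchmark <- function(sim, p_test, seed, p_train = 0.1,
                           train_frac = 0.8) {
  if (p_test <= 0 || p_test >= 1) {
    stop("`p_test` must lie in (0, 1)", call. = FALSE)
  }
  truth_adj <- NULL
  if (inherits(sim, "synthetic_dataset")) {
    truth_adj <- sim$true_adjacency
    ds <- sim$dataset
  } else {
    ds <- sim
  }
  stopifnot(inherits(ds, "ts_dataset"))
  n <- nrow(ds$values)
  n_train <- floor(train_frac * n)
  if (n_train < 2L || n - n_train < 2L) {
    stop("series too short for a train/test split", call. = FALSE)
  }
  idx_train <- seq_len(n_train)
  idx_test <- (n_train + 1L):n
  slice <- function(idx) {
    ts_dataset(ds$values[idx, , drop = FALSE], ds$timestamps[idx],
               ds$attribute_names)
  }
  seeds <- derive_seeds(seed, 2)
  train_truth <- slice(idx_train)
  test_truth <- slice(idx_test)
  train_drop <- inject_missing(train_truth, p_train, seeds[1])
  test_drop <- inject_missing(test_truth, p_test, seeds[2])
  structure(
    list(
      train = list(truth = train_truth, corrupted = train_drop$corrupted,
                   eval_mask = train_drop$eval_mask),
      test = list(truth = test_truth, corrupted = test_drop$corrupted,
                  eval_mask = test_drop$eval_mask),
      true_adjacency = truth_adj,
      config = list(p_test = p_test, p_train = p_train,
                    train_frac = train_frac, seed = seed)
    ),
    class = "imputation_benchmark"
  )
}
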