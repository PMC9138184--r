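# Scoring of imputations on artificially dropped entries (RMSE/MAE),
# closed-form statistical baselines, causal-recovery AUROC and the
# missing-rate sweep that mirrors the method-by-rate evaluation tables.

#' Imputation error on evaluation-dropped entries
#'
#' Root-mean-square and mean-absolute error computed only over entries where
#' `eval_mask = 1`, i.e. the artificially dropped positions for which ground
#' truth is known. By convention both are computed on the normalized 0-1
#' scale.
#'
#' @param truth,imputed numeric arrays of equal shape.
#' @param eval_mask binary array marking scored entries (at least one 1).
#' @return Nonnegative scalar; `rmse >= mae` always.
#' @examples
#' rmse(c(1, 3), c(2, 2), c(1, 1))  # 1
#' @export
rmse <- function(truth, imputed, eval_mask) {
  e <- scored_errors(truth, imputed, eval_mask)
  sqrt(mean(e^2))
}

#' @rdname rmse
#' @export
mae <- function(truth, imputed, eval_mask) {
  e <- scored_errors(truth, imputed, eval_mask)
  mean(abs(e))
}

scored_errors <- function(truth, imputed, eval_mask) {
  if (!all(dim(as.matrix(truth)) == dim(as.matrix(imputed)))) {
    stop("`truth` and `imputed` must have equal shape", call. = FALSE)
  }
  sel <- eval_mask == 1
  if (!any(sel)) stop("`eval_mask` marks no entries to score", call. = FALSE)
  (as.matrix(truth) - as.matrix(imputed))[sel]
}

#' Statistical imputation baselines
#'
#' Fills absent entries with a closed-form rule computed from the observed
#' entries of each attribute: `"zero"`, `"mean"`, `"median"`, `"random"`
#' (uniform draws on `[0, 1]`, for normalized data) or `"locf"` (last
#' observation carried forward, falling back to the attribute mean before the
#' first observation). Observed entries are untouched.
#'
#' @param ds a normalized [ts_dataset()].
#' @param method one of `"zero"`, `"mean"`, `"median"`, `"random"`, `"locf"`.
#' @param seed integer seed (used by `"random"` only).
#' @return A completed [ts_dataset()].
#' @export
baseline_impute <- function(ds, method = c("zero", "mean", "median",
                                           "random", "locf"), seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "ts_dataset"))
  vals <- ds$values
  n <- nrow(vals); d <- ncol(vals)
  if (method != "zero") {
    for (j in seq_len(d)) {
      if (!any(ds$mask[, j] == 1L)) {
        stop("attribute `", ds$attribute_names[j],
             "` has no observed entries", call. = FALSE)
      }
    }
  }
  if (method == "random") {
    draws <- with_seed(seed, stats::runif(sum(ds$mask == 0L)))
  }
  di <- 0L
  for (j in seq_len(d)) {
    miss <- which(ds$mask[, j] == 0L)
    if (length(miss) == 0L) next
    obs <- vals[ds$mask[, j] == 1L, j]
    fill <- switch(method,
      zero = rep(0, length(miss)),
      mean = rep(mean(obs), length(miss)),
      median = rep(stats::median(obs), length(miss)),
      random = draws[di + seq_along(miss)],
      locf = {
        col <- vals[, j]
        col[ds$mask[, j] == 0L] <- NA_real_
        last <- mean(obs)  # fallback before the first observation
        out <- numeric(length(miss))
        mi <- 1L
        for (t in seq_len(n)) {
          if (!is.na(col[t])) {
            last <- col[t]
          } else if (mi <= length(miss) && miss[mi] == t) {
            out[mi] <- last
            mi <- mi + 1L
          }
        }
        out
      }
    )
    if (method == "random") di <- di + length(miss)
    vals[miss, j] <- fill
  }
  ts_dataset(vals, ds$timestamps, ds$attribute_names)
}

#' Causal-recovery AUROC
#'
#' Area under the ROC curve of the estimated adjacency scores against the
#' binary true edge set, ranking off-diagonal entries only (self-edges are
#' excluded from scoring).
#'
#' @param A_est nonnegative score matrix (e.g. [extract_adjacency()]).
#' @param A_true binary matrix of true directed edges, same shape.
#' @return Scalar in `[0, 1]`.
#' @export
causal_recovery_auroc <- function(A_est, A_true) {
  if (!all(dim(A_est) == dim(A_true))) {
    stop("`A_est` and `A_true` must have equal shape", call. = FALSE)
  }
  off <- row(A_true) != col(A_true)
  labels <- as.integer(A_true[off] != 0)
  scores <- A_est[off]
  if (all(labels == 0L) || all(labels == 1L)) {
    stop("AUROC undefined: true edge set is trivial off-diagonal",
         call. = FALSE)
  }
  as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c(0, 1), direction = "<", quiet = TRUE
  )))
}

#' Missing-rate sweep over imputation methods
#'
#' For every drop rate in `p_list` and every method, corrupts the benchmark's
#' test split at that rate, imputes, and scores RMSE/MAE on the dropped
#' entries; results are averaged over `seeds`. Methods are either baseline
#' names (see [baseline_impute()]) or `"cgcn"`, which trains the full model
#' on the benchmark's training split (once per seed) and imputes with it.
#'
#' @param benchmark a [make_benchmark()] bundle.
#' @param methods character vector of methods.
#' @param p_list drop rates in `(0, 1)`.
#' @param seeds integer vector of seeds.
#' @param train_args list of arguments forwarded to [train_imputer()] for the
#'   `"cgcn"` method.
#' @return An `eval_report` tibble with columns `method`, `missing_rate`,
#'   `rmse`, `mae`, `n_scored`, `seeds`.
#' @export
sweep_missing_rates <- function(benchmark, methods, p_list, seeds = 1,
                                train_args = list()) {
  stopifnot(inherits(benchmark, "imputation_benchmark"))
  if (any(p_list <= 0 | p_list >= 1)) {
    stop("`p_list` rates must lie in (0, 1)", call. = FALSE)
  }
  if (length(seeds) < 1L) stop("at least one seed required", call. = FALSE)
  test_truth <- benchmark$test$truth

  fits <- list()
  if ("cgcn" %in% methods) {
    for (s in seq_along(seeds)) {
      args <- c(list(dataset = benchmark$train$corrupted, seed = seeds[s]),
                train_args)
      fits[[s]] <- do.call(train_imputer, args)
    }
  }

  rows <- list()
  for (p in p_list) {
    for (m in methods) {
      rs <- ms <- ns <- numeric(length(seeds))
      for (s in seq_along(seeds)) {
        drop <- inject_missing(test_truth, p, seeds[s])
        completed <- if (m == "cgcn") {
          impute_missing(fits[[s]], drop$corrupted, denormalize = FALSE)
        } else {
          baseline_impute(drop$corrupted, m, seed = seeds[s])
        }
        rs[s] <- rmse(test_truth$values, completed$values, drop$eval_mask)
        ms[s] <- mae(test_truth$values, completed$values, drop$eval_mask)
        ns[s] <- sum(drop$eval_mask)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = m, missing_rate = p, rmse = mean(rs), mae = mean(ms),
        n_scored = sum(ns), seeds = paste(seeds, collapse = ";")
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("eval_report", class(out))
  out
}
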