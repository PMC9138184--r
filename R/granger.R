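# Neural Granger causal discovery: one component-wise LSTM predictor per
# target attribute, trained with a group-lasso penalty on the columns of the
# stacked input matrix W. The directed adjacency A[i, j] is the squared
# Frobenius norm of the input-weight column group of attribute i in target
# j's predictor.
#
# Gate blocks are stacked in the order (f, i, o, c): rows 1..H of W/U/b act
# on the forget gate, H+1..2H the input gate, 2H+1..3H the output gate,
# 3H+1..4H the cell candidate.

granger_init_target <- function(d, hidden, seed) {
  with_seed(seed, {
    sc <- 0.1
    list(
      W = matrix(stats::rnorm(4 * hidden * d, sd = sc), 4 * hidden, d),
      U = matrix(stats::rnorm(4 * hidden * hidden, sd = sc), 4 * hidden, hidden),
      b = numeric(4 * hidden),
      v = stats::rnorm(hidden, sd = sc),
      c0 = 0
    )
  })
}

#' Initialize a neural Granger model
#'
#' Creates `d` independent single-layer LSTM predictors, one per target
#' attribute, each taking all `d` attributes as input.
#'
#' @param d number of attributes.
#' @param hidden hidden state size `H` of each predictor (default 16).
#' @param lambda group-lasso penalty weight (default 0.01).
#' @param seed integer seed for parameter initialization.
#' @return A list of class `granger_model` with per-target parameter lists
#'   (`W` stacked `4H x d`, `U` `4H x H`, `b`, output head `v`, `c0`), plus
#'   `hidden`, `lambda` and `d`.
#' @export
granger_init <- function(d, hidden = 16, lambda = 0.01, seed = 1) {
  seeds <- derive_seeds(seed, d)
  structure(
    list(
      targets = lapply(seq_len(d), function(j) {
        granger_init_target(d, hidden, seeds[j])
      }),
      hidden = hidden, lambda = lambda, d = d
    ),
    class = "granger_model"
  )
}

#' Single LSTM cell update
#'
#' Applies the standard LSTM gate equations: sigmoid forget/input/output
#' gates, tanh cell candidate, elementwise state update
#' `c_t = f * c_prev + i * tanh_candidate`, `h_t = o * tanh(c_t)`.
#'
#' @param x_t input vector (length `d`).
#' @param h_prev,c_prev previous hidden and cell state (length `H`).
#' @param params list with `W` (`4H x d`), `U` (`4H x H`), `b` (`4H`);
#'   gate blocks stacked in the order forget, input, output, candidate.
#' @return A list with updated `h` and `c` (length `H`).
#' @export
lstm_cell <- function(x_t, h_prev, c_prev, params) {
  H <- length(h_prev)
  if (nrow(params$W) != 4 * H || ncol(params$W) != length(x_t) ||
      any(dim(params$U) != c(4 * H, H)) || length(c_prev) != H) {
    stop("parameter shapes inconsistent with hidden/input sizes",
         call. = FALSE)
  }
  z <- drop(params$W %*% x_t + params$U %*% h_prev) + params$b
  f <- sigmoid(z[seq_len(H)])
  i <- sigmoid(z[H + seq_len(H)])
  o <- sigmoid(z[2 * H + seq_len(H)])
  g <- tanh(z[3 * H + seq_len(H)])
  c_t <- f * c_prev + i * g
  list(h = o * tanh(c_t), c = c_t)
}

#' One-step-ahead predictions for one target attribute
#'
#' Runs target `j`'s LSTM over the window and decodes the hidden state
#' linearly. The prediction at time `t` uses inputs strictly before `t`, so
#' the first prediction is for the second timestamp; the first element of the
#' returned vector is `NA`.
#'
#' @param model a [granger_init()] / [fit_granger()] model.
#' @param j target attribute index.
#' @param X_past numeric `L x d` matrix, fully valued (absent entries already
#'   zero-filled).
#' @return Numeric vector of length `L`: `NA` followed by predictions for
#'   timestamps `2..L`.
#' @export
predict_series <- function(model, j, X_past) {
  X_past <- as.matrix(X_past)
  L <- nrow(X_past)
  if (L < 2) stop("window must contain at least 2 timestamps", call. = FALSE)
  p <- model$targets[[j]]
  Xb <- array(X_past, c(1L, L, ncol(X_past)))
  fwd <- granger_forward_batch(p, Xb, model$hidden)
  c(NA_real_, drop(fwd$pred))
}

#' Group-lasso penalty of a stacked input matrix
#'
#' Sum over input attributes of the unsquared Euclidean norm of the
#' corresponding column group of `W`.
#'
#' @param W_stacked `4H x d` stacked gate input matrix.
#' @return Nonnegative scalar.
#' @examples
#' W <- matrix(0, 4, 2); W[1:2, 1] <- c(3, 4)
#' group_penalty(W)  # 5
#' @export
group_penalty <- function(W_stacked) {
  sum(sqrt(colSums(as.matrix(W_stacked)^2)))
}

#' Granger training loss on one window
#'
#' Sum over targets of the masked squared one-step prediction error (only
#' timestamps where the target is observed contribute), plus `lambda` times
#' the summed group penalties of all targets' input matrices.
#'
#' @param model a `granger_model`.
#' @param window a normalized [ts_dataset()] window.
#' @param lambda nonnegative penalty weight.
#' @return Scalar loss.
#' @export
granger_loss <- function(model, window, lambda) {
  if (lambda < 0) stop("`lambda` must be nonnegative", call. = FALSE)
  X <- zero_fill(window)
  L <- nrow(X)
  sse <- 0
  for (j in seq_len(model$d)) {
    pred <- predict_series(model, j, X)
    m <- window$mask[2:L, j]
    res <- (window$values[2:L, j] - pred[2:L])
    res[m == 0L] <- 0
    sse <- sse + sum(res^2)
  }
  pen <- sum(vapply(model$targets, function(p) group_penalty(p$W), 0))
  sse + lambda * pen
}

#' Extract the directed causal adjacency matrix
#'
#' `A[i, j]` is the squared Frobenius norm of the column group of target
#' `j`'s stacked input matrix that multiplies input attribute `i`. Entries
#' are nonnegative; `A` is zero exactly when all input weights are zero.
#' Recurrent weights and biases do not enter.
#'
#' @param model a `granger_model`.
#' @return Nonnegative `d x d` matrix; rows index source attributes, columns
#'   targets.
#' @export
extract_adjacency <- function(model) {
  d <- model$d
  A <- matrix(0, d, d)
  for (j in seq_len(d)) {
    A[, j] <- colSums(model$targets[[j]]$W^2)
  }
  A
}

# ---- batched forward/backward engine ---------------------------------------
# X is a B x L x d array of zero-filled windows. The forward caches every
# intermediate needed by backprop. Predictions pred[b, t] target timestamp
# t + 1 (columns 1..L-1 predict timestamps 2..L).

granger_forward_batch <- function(p, X, H) {
  B <- dim(X)[1]; L <- dim(X)[2]
  hs <- cs <- fs <- is_ <- os <- gs <- tcs <- vector("list", L - 1L)
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  pred <- matrix(0, B, L - 1L)
  tW <- t(p$W); tU <- t(p$U)
  for (t in seq_len(L - 1L)) {
    xt <- X[, t, , drop = FALSE]
    dim(xt) <- c(B, dim(X)[3])
    z <- xt %*% tW + h %*% tU
    z <- sweep(z, 2L, p$b, "+")
    f <- sigmoid(z[, seq_len(H), drop = FALSE])
    i <- sigmoid(z[, H + seq_len(H), drop = FALSE])
    o <- sigmoid(z[, 2 * H + seq_len(H), drop = FALSE])
    g <- tanh(z[, 3 * H + seq_len(H), drop = FALSE])
    cc_new <- f * cc + i * g
    tc <- tanh(cc_new)
    h_new <- o * tc
    fs[[t]] <- f; is_[[t]] <- i; os[[t]] <- o; gs[[t]] <- g
    tcs[[t]] <- tc; cs[[t]] <- cc; hs[[t]] <- h  # states *entering* step t
    cc <- cc_new; h <- h_new
    pred[, t] <- h %*% p$v + p$c0
    attr(fs[[t]], "h_out") <- h  # exiting hidden state, used by the decoder
  }
  list(pred = pred, f = fs, i = is_, o = os, g = gs, tc = tcs,
       h_in = hs, c_in = cs, B = B, L = L)
}

granger_backward_batch <- function(p, X, cache, dpred, H) {
  B <- cache$B; L <- cache$L
  d <- dim(X)[3]
  dW <- matrix(0, 4 * H, d)
  dU <- matrix(0, 4 * H, H)
  db <- numeric(4 * H)
  dv <- numeric(H)
  dc0 <- 0
  dh <- matrix(0, B, H)
  dc <- matrix(0, B, H)
  for (t in (L - 1L):1L) {
    h_out <- attr(cache$f[[t]], "h_out")
    # decoder gradient at this step
    dp <- dpred[, t]
    dv <- dv + drop(crossprod(h_out, dp))
    dc0 <- dc0 + sum(dp)
    dh <- dh + tcrossprod(dp, p$v)
    f <- cache$f[[t]]; i <- cache$i[[t]]; o <- cache$o[[t]]
    g <- cache$g[[t]]; tc <- cache$tc[[t]]
    do_ <- dh * tc
    dc <- dc + dh * o * (1 - tc^2)
    df <- dc * cache$c_in[[t]]
    di <- dc * g
    dg <- dc * i
    dc_prev <- dc * f
    dz <- cbind(df * f * (1 - f), di * i * (1 - i),
                do_ * o * (1 - o), dg * (1 - g^2))
    xt <- X[, t, , drop = FALSE]; dim(xt) <- c(B, d)
    dW <- dW + crossprod(dz, xt)
    dU <- dU + crossprod(dz, cache$h_in[[t]])
    db <- db + colSums(dz)
    dh <- dz %*% p$U
    dc <- dc_prev
  }
  list(W = dW, U = dU, b = db, v = dv, c0 = dc0)
}

# Masked SSE loss + gradients for all targets over a batch of windows.
# windows: list of equal-length groups, each a list(X = B x L x d array,
# vals = B x L x d array, mask = B x L x d). Returns loss (SSE only) and
# per-target grads.
granger_sse_grads <- function(model, groups) {
  d <- model$d; H <- model$hidden
  grads <- lapply(model$targets, par_zeros_like)
  sse <- 0
  for (grp in groups) {
    X <- grp$X; L <- dim(X)[2]
    for (j in seq_len(d)) {
      p <- model$targets[[j]]
      fwd <- granger_forward_batch(p, X, H)
      tgt <- grp$vals[, 2:L, j, drop = FALSE]
      dim(tgt) <- dim(fwd$pred)
      msk <- grp$mask[, 2:L, j, drop = FALSE]
      dim(msk) <- dim(fwd$pred)
      res <- (fwd$pred - tgt) * msk
      sse <- sse + sum(res^2)
      dpred <- 2 * res
      g <- granger_backward_batch(p, X, fwd, dpred, H)
      grads[[j]] <- par_map(`+`, grads[[j]], g)
    }
  }
  list(sse = sse, grads = grads)
}

# Pack a list of ts_dataset windows into equal-length batch groups.
pack_windows <- function(windows) {
  lens <- vapply(windows, function(w) nrow(w$values), 0L)
  groups <- list()
  for (L in unique(lens)) {
    sel <- windows[lens == L]
    B <- length(sel)
    d <- ncol(sel[[1]]$values)
    X <- vals <- array(0, c(B, L, d))
    mask <- array(0L, c(B, L, d))
    delta <- array(0, c(B, L, d))
    for (b in seq_len(B)) {
      w <- sel[[b]]
      X[b, , ] <- zero_fill(w)
      v <- w$values; v[w$mask == 0L] <- 0
      vals[b, , ] <- v
      mask[b, , ] <- w$mask
      delta[b, , ] <- compute_time_lag(w$timestamps, w$mask)
    }
    groups[[length(groups) + 1L]] <- list(X = X, vals = vals, mask = mask,
                                          delta = delta, L = L, B = B)
  }
  groups
}

#' Fit the neural Granger causal-discovery model
#'
#' Minimizes the summed masked one-step prediction error plus the group-lasso
#' penalty by Adam on the smooth part with a proximal group soft-threshold on
#' the input-weight column groups after every step (so irrelevant input
#' groups are driven exactly to zero). Deterministic given `seed`.
#'
#' @param dataset a normalized [ts_dataset()].
#' @param hidden LSTM hidden size per target (default 16).
#' @param lambda group-lasso weight (default 0.01).
#' @param lr Adam learning rate (default 5e-3).
#' @param epochs training epochs (default 100).
#' @param window_length window length for batching (default 48).
#' @param seed integer seed.
#' @return An object of class `granger_fit`: the fitted `granger_model`
#'   (element `model`), adjacency `A`, per-epoch `history` tibble
#'   (`epoch`, `sse`, `penalty`, `loss`) and the configuration.
#' @export
fit_granger <- function(dataset, hidden = 16, lambda = 0.01, lr = 5e-3,
                        epochs = 100, window_length = 48, seed = 1) {
  stopifnot(inherits(dataset, "ts_dataset"))
  if (lambda < 0) stop("`lambda` must be nonnegative", call. = FALSE)
  d <- ncol(dataset$values)
  groups <- pack_windows(ts_segment(dataset, window_length))
  model <- granger_init(d, hidden = hidden, lambda = lambda, seed = seed)
  state <- adam_init(model$targets)
  history <- matrix(0, epochs, 3L)
  for (ep in seq_len(epochs)) {
    sg <- granger_sse_grads(model, groups)
    if (!is.finite(sg$sse)) {
      stop("training diverged (non-finite loss) at epoch ", ep, call. = FALSE)
    }
    upd <- adam_step(model$targets, sg$grads, state, lr)
    model$targets <- upd$params
    state <- upd$state
    # proximal group soft-threshold on the input-weight column groups
    if (lambda > 0) {
      for (j in seq_len(d)) {
        W <- model$targets[[j]]$W
        for (i in seq_len(d)) {
          W[, i] <- group_soft_threshold(W[, i], lr * lambda)
        }
        model$targets[[j]]$W <- W
      }
    }
    pen <- sum(vapply(model$targets, function(p) group_penalty(p$W), 0))
    history[ep, ] <- c(sg$sse, pen, sg$sse + lambda * pen)
  }
  structure(
    list(
      model = model,
      A = extract_adjacency(model),
      history = tibble::tibble(
        epoch = seq_len(epochs), sse = history[, 1],
        penalty = history[, 2], loss = history[, 3]
      ),
      config = list(hidden = hidden, lambda = lambda, lr = lr,
                    epochs = epochs, window_length = window_length,
                    seed = seed),
      attribute_names = dataset$attribute_names
    ),
    class = "granger_fit"
  )
}

#' @export
print.granger_fit <- function(x, ...) {
  cat(sprintf(
    "<granger_fit: %d attributes, hidden = %d, lambda = %g, %d epochs>\n",
    ncol(x$A), x$config$hidden, x$config$lambda, x$config$epochs
  ))
  invisible(x)
}

#' Write / read an adjacency matrix as a delimited table
#'
#' @param A `d x d` adjacency matrix.
#' @param path output path.
#' @param attribute_names optional names for the header row/column.
#' @return `path` invisibly, or the matrix for the reader.
#' @export
write_adjacency <- function(A, path, attribute_names = NULL) {
  nms <- attribute_names %||% colnames(A) %||% paste0("V", seq_len(ncol(A)))
  df <- tibble::as_tibble(as.data.frame(A, row.names = NULL))
  names(df) <- nms
  df <- dplyr::bind_cols(tibble::tibble(attribute = nms), df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  nms <- df$attribute
  A <- as.matrix(df[, -1, drop = FALSE])
  rownames(A) <- nms
  A
}
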