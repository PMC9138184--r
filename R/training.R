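# Multi-task objective and end-to-end joint training: weighted sum of the
# Granger prediction loss, the masked reconstruction loss and the
# total-variation smoothness loss, optimized by Adam with the group-lasso
# penalty handled proximally. The adjacency is recomputed from the current
# Granger input weights every step; when `joint_causality` is on, gradients
# of the reconstruction losses flow back through the normalized adjacency
# into the Granger weights.

#' Masked reconstruction loss
#'
#' Mean (default) of squared differences over entries where `mask = 1`;
#' unobserved entries never contribute. Returns 0 when nothing is observed.
#'
#' @param x,x_hat numeric arrays of equal shape.
#' @param mask binary array of the same shape.
#' @param reduction `"mean"` (default) or `"sum"`.
#' @return Nonnegative scalar.
#' @export
masked_loss <- function(x, x_hat, mask, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (!all(dim(as.matrix(x)) == dim(as.matrix(x_hat)))) {
    stop("`x` and `x_hat` must have equal shape", call. = FALSE)
  }
  n_obs <- sum(mask == 1)
  if (n_obs == 0) return(0)
  sq <- ((x - x_hat)^2)[mask == 1]
  if (reduction == "mean") sum(sq) / n_obs else sum(sq)
}

#' Total-variation loss
#'
#' Sum over attributes of the absolute first differences of the
#' reconstruction along time. Penalizing it smooths noise while preserving
#' jumps; it is invariant to adding a constant.
#'
#' @param x_hat `n x d` reconstructed matrix.
#' @return Nonnegative scalar; 0 when `n < 2`.
#' @examples
#' tv_loss(matrix(c(1, 2, 4), 3))  # 3
#' @export
tv_loss <- function(x_hat) {
  x_hat <- as.matrix(x_hat)
  if (nrow(x_hat) < 2L) return(0)
  sum(abs(diff(x_hat)))
}

#' Weighted total objective
#'
#' `w_ng * l_ng + w_rec * l_rec + w_tv * l_tv`, the multi-task training
#' objective combining causal-prediction, masked-reconstruction and
#' total-variation components. Setting a weight to zero ablates that
#' component.
#'
#' @param l_ng,l_rec,l_tv finite component losses.
#' @param weights named numeric vector with nonnegative elements `ng`,
#'   `rec`, `tv`.
#' @return Scalar.
#' @export
total_loss <- function(l_ng, l_rec, l_tv, weights = c(ng = 1, rec = 1, tv = 1)) {
  weights <- check_weights(weights)
  weights[["ng"]] * l_ng + weights[["rec"]] * l_rec + weights[["tv"]] * l_tv
}

check_weights <- function(weights) {
  if (is.null(names(weights))) names(weights) <- c("ng", "rec", "tv")
  if (!all(c("ng", "rec", "tv") %in% names(weights))) {
    stop("`weights` must supply ng, rec and tv", call. = FALSE)
  }
  if (any(weights < 0)) stop("loss weights must be nonnegative", call. = FALSE)
  weights
}

# ---- joint loss + gradients -------------------------------------------------

# Computes the three component losses and, when `grad = TRUE`, the analytic
# gradients w.r.t. every Granger and imputer parameter. `include_penalty`
# adds the group-lasso term (and its subgradient) to l_ng; training leaves it
# out and applies the proximal operator instead.
joint_loss_grads <- function(gmodel, imodel, groups, weights,
                             joint_causality = TRUE, adjacency = NULL,
                             include_penalty = FALSE, grad = TRUE) {
  weights <- check_weights(weights)
  d <- imodel$d
  sigma <- imodel$sigma
  A <- adjacency %||% extract_adjacency(gmodel)
  Ahat <- normalized_adjacency(A)

  # Granger component
  l_ng <- 0
  g_grads <- NULL
  if (!is.null(gmodel)) {
    if (grad) {
      sg <- granger_sse_grads(gmodel, groups)
      l_ng <- sg$sse
      g_grads <- lapply(sg$grads, function(gl) {
        par_map(function(x) x * weights[["ng"]], gl)
      })
    } else {
      l_ng <- sum(vapply(groups, function(grp) {
        s <- 0
        L <- grp$L
        for (j in seq_len(gmodel$d)) {
          fwd <- granger_forward_batch(gmodel$targets[[j]], grp$X,
                                       gmodel$hidden)
          tgt <- grp$vals[, 2:L, j, drop = FALSE]; dim(tgt) <- dim(fwd$pred)
          msk <- grp$mask[, 2:L, j, drop = FALSE]; dim(msk) <- dim(fwd$pred)
          s <- s + sum(((fwd$pred - tgt) * msk)^2)
        }
        s
      }, 0))
    }
    if (include_penalty) {
      lam <- gmodel$lambda
      pen <- sum(vapply(gmodel$targets, function(p) group_penalty(p$W), 0))
      l_ng <- l_ng + lam * pen
      if (grad) {
        for (j in seq_len(gmodel$d)) {
          W <- gmodel$targets[[j]]$W
          nrm <- sqrt(colSums(W^2))
          sub <- sweep(W, 2L, ifelse(nrm > 0, nrm, 1), "/")
          sub[, nrm == 0] <- 0
          g_grads[[j]]$W <- g_grads[[j]]$W + weights[["ng"]] * lam * sub
        }
      }
    }
  }

  # reconstruction + TV components; both are normalized by their entry
  # counts so the loss weights are independent of the problem size
  n_obs <- sum(vapply(groups, function(grp) sum(grp$mask), 0))
  n_dif <- sum(vapply(groups, function(grp) grp$B * (grp$L - 1) * d, 0))
  sse_rec <- 0
  tv_sum <- 0
  i_grads <- if (grad) par_zeros_like(imodel$params) else NULL
  dAhat <- matrix(0, d, d)
  for (grp in groups) {
    fwd <- imputer_forward_batch(imodel$params, Ahat, grp, sigma,
                                 imodel$hidden, imodel$d_gcn)
    res <- (fwd$xhat - grp$vals) * grp$mask
    sse_rec <- sse_rec + sum(res^2)
    dif <- fwd$xhat[, 2:grp$L, , drop = FALSE] -
      fwd$xhat[, 1:(grp$L - 1L), , drop = FALSE]
    tv_sum <- tv_sum + sum(abs(dif))
    if (grad) {
      dxhat <- weights[["rec"]] * 2 * res / max(n_obs, 1)
      sgn <- sign(dif) * (weights[["tv"]] / max(n_dif, 1))
      dxhat[, 2:grp$L, ] <- dxhat[, 2:grp$L, , drop = FALSE] + sgn
      dxhat[, 1:(grp$L - 1L), ] <- dxhat[, 1:(grp$L - 1L), , drop = FALSE] -
        sgn
      bwd <- imputer_backward_batch(imodel$params, Ahat, grp, fwd, dxhat,
                                    sigma)
      i_grads <- par_map(`+`, i_grads, bwd$grads)
      dAhat <- dAhat + bwd$dAhat
    }
  }
  l_rec <- sse_rec / max(n_obs, 1)
  l_tv <- tv_sum / max(n_dif, 1)

  # route adjacency gradients into the Granger input weights
  if (grad && joint_causality && is.null(adjacency) && !is.null(gmodel)) {
    dA <- normalized_adjacency_backward(A, dAhat)
    for (j in seq_len(gmodel$d)) {
      W <- gmodel$targets[[j]]$W
      g_grads[[j]]$W <- g_grads[[j]]$W +
        sweep(2 * W, 2L, dA[, j], "*")
    }
  }

  total <- total_loss(l_ng, l_rec, l_tv, weights)
  list(l_ng = l_ng, l_rec = l_rec, l_tv = l_tv, total = total,
       g_grads = g_grads, i_grads = i_grads, A = A)
}

#' Train the imputation model end-to-end
#'
#' Jointly optimizes the neural Granger predictors and the imputation
#' network under the weighted multi-task objective using full-batch Adam.
#' The adjacency is recomputed from the current Granger input weights at
#' every step; with `joint_causality = TRUE` the reconstruction losses also
#' backpropagate into the Granger weights through the normalized adjacency
#' (otherwise the adjacency is treated as detached). The group-lasso penalty
#' is applied proximally (column-group soft-thresholding) after each Adam
#' step, scaled by `weights["ng"] * lambda`.
#'
#' @param dataset a normalized [ts_dataset()] (values in `[0, 1]`, missing
#'   entries absent).
#' @param hidden decay-LSTM hidden size (default 64).
#' @param granger_hidden per-target Granger LSTM hidden size (default 16).
#' @param lambda group-lasso weight (default 0.01).
#' @param weights named nonnegative loss weights `c(ng, rec, tv)`,
#'   default all 1.
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs training epochs (default 100).
#' @param window_length window length for batching (default 48).
#' @param d_gcn graph-convolution features per node (default 1).
#' @param sigma GCN activation (default `"identity"`).
#' @param joint_causality logical; let reconstruction gradients flow into the
#'   Granger weights through the adjacency (default `TRUE`).
#' @param pretrain_granger_epochs epochs of Granger-only pretraining before
#'   joint training (default 0 = fully joint).
#' @param adjacency optional fixed `d x d` nonnegative adjacency; when given
#'   the Granger submodel is still trained on its own loss (if
#'   `weights["ng"] > 0`) but the network uses this matrix.
#' @param scaler optional [fit_scaler()] result stored with the model so
#'   [impute_missing()] can denormalize.
#' @param seed integer seed; training is deterministic given the seed.
#' @return An object of class `cgcn_fit` with elements `granger`,
#'   `imputer`, `A`, `history` (tibble of per-epoch component losses),
#'   `config`, `scaler`.
#' @export
train_imputer <- function(dataset, hidden = 64, granger_hidden = 16,
                          lambda = 0.01, weights = c(ng = 1, rec = 1, tv = 1),
                          lr = 1e-3, epochs = 100, window_length = 48,
                          d_gcn = 1, sigma = "identity",
                          joint_causality = TRUE,
                          pretrain_granger_epochs = 0,
                          adjacency = NULL, scaler = NULL, seed = 1) {
  stopifnot(inherits(dataset, "ts_dataset"))
  weights <- check_weights(weights)
  if (epochs < 1) stop("`epochs` must be at least 1", call. = FALSE)
  d <- ncol(dataset$values)
  windows <- ts_segment(dataset, window_length)
  if (length(windows) < 1L) stop("dataset yields no windows", call. = FALSE)
  groups <- pack_windows(windows)

  seeds <- derive_seeds(seed, 2)
  gmodel <- granger_init(d, hidden = granger_hidden, lambda = lambda,
                         seed = seeds[1])
  imodel <- imputer_init(d, hidden = hidden, d_gcn = d_gcn, sigma = sigma,
                         seed = seeds[2])

  if (pretrain_granger_epochs > 0) {
    g_state <- adam_init(gmodel$targets)
    for (ep in seq_len(pretrain_granger_epochs)) {
      sg <- granger_sse_grads(gmodel, groups)
      upd <- adam_step(gmodel$targets, sg$grads, g_state, lr)
      gmodel$targets <- upd$params
      g_state <- upd$state
      gmodel <- prox_granger(gmodel, lr * lambda)
    }
  }

  state_g <- adam_init(gmodel$targets)
  state_i <- adam_init(imodel$params)
  hist <- matrix(0, epochs, 4L)
  for (ep in seq_len(epochs)) {
    jl <- joint_loss_grads(gmodel, imodel, groups, weights,
                           joint_causality = joint_causality,
                           adjacency = adjacency)
    if (!is.finite(jl$total)) {
      stop("training diverged (non-finite loss) at epoch ", ep,
           ": ng=", jl$l_ng, " rec=", jl$l_rec, " tv=", jl$l_tv,
           call. = FALSE)
    }
    hist[ep, ] <- c(jl$l_ng, jl$l_rec, jl$l_tv, jl$total)
    upd_i <- adam_step(imodel$params, jl$i_grads, state_i, lr)
    imodel$params <- upd_i$params
    state_i <- upd_i$state
    if (weights[["ng"]] > 0 || joint_causality) {
      upd_g <- adam_step(gmodel$targets, jl$g_grads, state_g, lr)
      gmodel$targets <- upd_g$params
      state_g <- upd_g$state
      if (weights[["ng"]] > 0 && lambda > 0) {
        gmodel <- prox_granger(gmodel, lr * weights[["ng"]] * lambda)
      }
    }
  }
  A <- if (is.null(adjacency)) extract_adjacency(gmodel) else adjacency
  structure(
    list(
      granger = gmodel,
      imputer = imodel,
      A = A,
      history = tibble::tibble(
        epoch = seq_len(epochs), l_ng = hist[, 1], l_rec = hist[, 2],
        l_tv = hist[, 3], total = hist[, 4]
      ),
      config = list(
        hidden = hidden, granger_hidden = granger_hidden, lambda = lambda,
        weights = weights, lr = lr, epochs = epochs,
        window_length = window_length, d_gcn = d_gcn, sigma = sigma,
        joint_causality = joint_causality,
        pretrain_granger_epochs = pretrain_granger_epochs, seed = seed
      ),
      scaler = scaler,
      attribute_names = dataset$attribute_names
    ),
    class = "cgcn_fit"
  )
}

prox_granger <- function(gmodel, tau) {
  for (j in seq_len(gmodel$d)) {
    W <- gmodel$targets[[j]]$W
    for (i in seq_len(ncol(W))) {
      W[, i] <- group_soft_threshold(W[, i], tau)
    }
    gmodel$targets[[j]]$W <- W
  }
  gmodel
}

#' @export
print.cgcn_fit <- function(x, ...) {
  cat(sprintf(
    "<cgcn_fit: %d attributes, hidden = %d, %d epochs, final loss %.4g>\n",
    length(x$attribute_names), x$config$hidden, x$config$epochs,
    x$history$total[nrow(x$history)]
  ))
  invisible(x)
}

#' Train under the evaluation dropout protocol
#'
#' Applies an MCAR drop of fraction `p_train` to the (already corrupted or
#' fully observed) training series before training, mirroring the protocol
#' where a portion of the training observations is hidden. The dropped-entry
#' ground truth is returned for monitoring only; the training loss sees only
#' the corrupted mask.
#'
#' @param dataset a normalized [ts_dataset()].
#' @param p_train training drop fraction in `[0, 1)`.
#' @param ... passed to [train_imputer()].
#' @param seed integer seed (drives both the drop and training).
#' @return A list with `fit` (a `cgcn_fit`), `eval_mask` (the dropped
#'   positions) and `truth` (the input dataset).
#' @export
train_with_dropout_protocol <- function(dataset, p_train, ..., seed = 1) {
  seeds <- derive_seeds(seed, 2)
  if (p_train > 0) {
    drop <- inject_missing(dataset, p_train, seeds[1])
    corrupted <- drop$corrupted
    eval_mask <- drop$eval_mask
  } else {
    corrupted <- dataset
    eval_mask <- matrix(0L, nrow(dataset$values), ncol(dataset$values))
  }
  fit <- train_imputer(corrupted, ..., seed = seeds[2])
  list(fit = fit, eval_mask = eval_mask, truth = dataset)
}

#' Impute missing entries with a trained model
#'
#' Runs the full forward pass (graph convolution with the model's adjacency,
#' time-decay LSTM, attention, reconstruction) over consecutive windows and
#' fills exactly the absent entries with the reconstruction; observed entries
#' pass through bit-identically. A trailing timestamp not covered by the
#' windowing is imputed from a final two-row window.
#'
#' @param fit a [train_imputer()] result.
#' @param dataset a normalized [ts_dataset()] with the same attributes the
#'   model was trained on.
#' @param denormalize map the completed series back to original units via the
#'   scaler stored in `fit` (default `TRUE` when one is stored).
#' @return A completed [ts_dataset()] with an all-ones mask.
#' @export
impute_missing <- function(fit, dataset, denormalize = !is.null(fit$scaler)) {
  stopifnot(inherits(fit, "cgcn_fit"), inherits(dataset, "ts_dataset"))
  d <- length(fit$attribute_names)
  if (ncol(dataset$values) != d) {
    stop("dataset has ", ncol(dataset$values), " attributes but the model ",
         "was trained on ", d, call. = FALSE)
  }
  n <- nrow(dataset$values)
  Ahat <- normalized_adjacency(fit$A)
  wl <- fit$config$window_length
  filled <- zero_fill(dataset)
  out <- dataset$values

  starts <- seq.int(1L, n, by = wl)
  spans <- list()
  for (s in starts) {
    e <- min(s + wl - 1L, n)
    if (e - s + 1L >= 2L) {
      spans[[length(spans) + 1L]] <- c(s, e)
    } else if (s > 1L) {
      spans[[length(spans) + 1L]] <- c(s - 1L, e)  # trailing single row
    }
  }
  for (sp in spans) {
    idx <- sp[1]:sp[2]
    w <- ts_dataset(dataset$values[idx, , drop = FALSE],
                    dataset$timestamps[idx], dataset$attribute_names)
    grp <- pack_windows(list(w))[[1]]
    fwd <- imputer_forward_batch(fit$imputer$params, Ahat, grp,
                                 fit$imputer$sigma, fit$imputer$hidden,
                                 fit$imputer$d_gcn)
    xh <- matrix(fwd$xhat[1, , ], length(idx), d)
    miss <- w$mask == 0L
    sub <- out[idx, , drop = FALSE]
    sub[miss] <- xh[miss]
    out[idx, ] <- sub
  }
  completed <- ts_dataset(out, dataset$timestamps, dataset$attribute_names)
  if (denormalize) {
    if (is.null(fit$scaler)) {
      stop("no scaler stored in the model; cannot denormalize", call. = FALSE)
    }
    completed <- invert_scaler(completed, fit$scaler)
  }
  completed
}

#' Save / load a trained model archive
#'
#' Serializes the full model (Granger and imputer parameters, adjacency,
#' scaler, attribute names, configuration) to a single file. A round-trip
#' reproduces model outputs bitwise.
#'
#' @param fit a `cgcn_fit`.
#' @param path file path for the archive.
#' @return `path` invisibly; `load_model()` returns the `cgcn_fit`.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "cgcn_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "cgcn_fit"))
  fit
}
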