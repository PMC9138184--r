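# The imputation network: degree-normalized causal graph convolution over
# attributes, a time-decay LSTM driven by the time-lag matrix, full temporal
# attention over the window, and a linear reconstruction head. Observed
# entries always pass through unchanged; only absent entries take the
# reconstruction.
#
# Decay-LSTM gate blocks are stacked (f, i, o, candidate), as in the Granger
# module.

#' Degree-normalized adjacency with self-loops
#'
#' Rescales a nonnegative adjacency so its largest entry is 1 (keeping edge
#' strengths comparable to the unit self-loop), adds the identity, and
#' symmetrically normalizes by the row-sum degree matrix:
#' `A_hat = D^(-1/2) (A/max(A) + I) D^(-1/2)`.
#'
#' @param A nonnegative `d x d` adjacency matrix (directed allowed).
#' @return `d x d` matrix with finite nonnegative entries.
#' @examples
#' normalized_adjacency(matrix(c(0, 1, 1, 0), 2))  # all entries 0.5
#' @export
normalized_adjacency <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("`A` must be square", call. = FALSE)
  if (any(A < 0)) stop("`A` must be nonnegative", call. = FALSE)
  mx <- max(A)
  if (mx > 0) A <- A / mx
  At <- A + diag(nrow(A))
  r <- rowSums(At)
  At / sqrt(outer(r, r))
}

# Backward pass of normalized_adjacency: given dL/dA_hat, return dL/dA.
# Uses the subgradient of the max-rescaling at the (first) argmax entry.
normalized_adjacency_backward <- function(A, dAhat) {
  d <- nrow(A)
  mx <- max(A)
  Ab <- if (mx > 0) A / mx else A
  At <- Ab + diag(d)
  r <- rowSums(At)
  Ahat <- At / sqrt(outer(r, r))
  # entry (u, v) of A_tilde enters A_hat directly and through both the row
  # degree r_u (scaling row u) and, as a row sum, the factor r_u scaling
  # column u; hence the row- and column-sum correction terms.
  gah <- dAhat * Ahat
  dAt <- dAhat / sqrt(outer(r, r)) -
    0.5 * matrix((rowSums(gah) + colSums(gah)) / r, d, d)
  if (mx > 0) {
    dA <- dAt / mx
    amax <- which.max(A)
    dA[amax] <- dA[amax] - sum(dAt * A) / mx^2
    dA
  } else {
    dAt
  }
}

#' Graph-convolution forward pass over a window
#'
#' Treats attributes as graph nodes: at each timestep the `d` attribute
#' values are mixed by `A_hat`, then each node's mixed scalar is expanded by
#' the shared feature transform `theta` (length `d_gcn`) and passed through
#' the activation. The output is flattened node-major, so with the default
#' `d_gcn = 1` it has the same shape as the input window.
#'
#' @param X_window fully valued `n x d` matrix (absent entries zero-filled).
#' @param A_hat normalized adjacency from [normalized_adjacency()].
#' @param theta numeric vector of per-node output features (default length 1).
#' @param sigma activation: one of `"identity"`, `"relu"`, `"tanh"`.
#' @return `n x (d * length(theta))` matrix.
#' @export
gcn_forward <- function(X_window, A_hat, theta = 1, sigma = "identity") {
  X_window <- as.matrix(X_window)
  if (ncol(X_window) != ncol(A_hat)) {
    stop("attribute count of `X_window` must match `A_hat`", call. = FALSE)
  }
  mixed <- X_window %*% t(A_hat)
  k <- length(theta)
  d <- ncol(mixed)
  out <- mixed[, rep(seq_len(d), each = k), drop = FALSE] *
    matrix(rep(theta, d), nrow(mixed), d * k, byrow = TRUE)
  act_fun(sigma)(out)
}

act_fun <- function(sigma) {
  switch(sigma,
    identity = function(x) x,
    relu = function(x) pmax(x, 0),
    tanh = tanh,
    stop("unknown activation `", sigma, "`", call. = FALSE)
  )
}

act_grad <- function(sigma, pre) {
  switch(sigma,
    identity = array(1, dim(pre)),
    relu = (pre > 0) * 1,
    tanh = 1 - tanh(pre)^2
  )
}

#' Time-decay vector from the time-lag matrix
#'
#' `alpha_t = 1 / exp(max(0, W_alpha delta_t + b_alpha))` elementwise: a
#' per-hidden-unit factor in `(0, 1]` that shrinks the recurrent hidden state
#' the longer attributes have gone unobserved.
#'
#' @param delta_t nonnegative time-lag vector (length `d`).
#' @param W_alpha `hidden x d` decay weight matrix.
#' @param b_alpha length-`hidden` bias.
#' @return Numeric vector in `(0, 1]` of length `hidden`.
#' @export
decay_vector <- function(delta_t, W_alpha, b_alpha) {
  exp(-pmax(0, drop(W_alpha %*% delta_t) + b_alpha))
}

#' One step of the time-decay LSTM
#'
#' The previous hidden state is decayed elementwise, `h' = alpha_t * h_prev`,
#' and a standard LSTM update is applied to the concatenated input
#' `[h'; hg_t]` (decayed hidden state and graph-convolution output). The cell
#' state is not decayed.
#'
#' @param h_prev,s_prev previous hidden and cell state (length `K`).
#' @param hg_t graph-convolution features at this timestep.
#' @param alpha_t decay vector in `(0, 1]` (length `K`).
#' @param params list with `Wg` (`4K x (K + length(hg_t))`) and `bg` (`4K`);
#'   gate blocks stacked forget, input, output, candidate.
#' @return List with updated `h` and `s`.
#' @export
decay_lstm_step <- function(h_prev, s_prev, hg_t, alpha_t, params) {
  K <- length(h_prev)
  if (ncol(params$Wg) != K + length(hg_t) || nrow(params$Wg) != 4 * K ||
      length(s_prev) != K) {
    stop("parameter shapes inconsistent", call. = FALSE)
  }
  hp <- alpha_t * h_prev
  z <- drop(params$Wg %*% c(hp, hg_t)) + params$bg
  f <- sigmoid(z[seq_len(K)])
  i <- sigmoid(z[K + seq_len(K)])
  o <- sigmoid(z[2 * K + seq_len(K)])
  g <- tanh(z[3 * K + seq_len(K)])
  s_t <- f * s_prev + i * g
  list(h = o * tanh(s_t), s = s_t)
}

#' Temporal attention over a window of hidden states
#'
#' Scores every pair of timesteps with `tanh(w1 . h_i + w2 . h_j)` and
#' softmax-normalizes over `i` within each row `j`, so each row of the
#' attention matrix sums to 1. The attended representation is
#' `H' = Atten %*% H_L`.
#'
#' @param H_L `T x K` matrix of decay-LSTM hidden states.
#' @param w_attn length-`2K` weight vector (first half scores the attended
#'   step, second half the query step).
#' @return List with `atten` (`T x T`, rows summing to 1) and `H` (`T x K`).
#' @export
temporal_attention <- function(H_L, w_attn) {
  H_L <- as.matrix(H_L)
  Tn <- nrow(H_L)
  if (Tn == 0L) stop("window must contain at least one timestep", call. = FALSE)
  K <- ncol(H_L)
  u <- drop(H_L %*% w_attn[seq_len(K)])        # attended (key) scores
  v <- drop(H_L %*% w_attn[K + seq_len(K)])    # query scores
  S <- tanh(outer(v, u, "+"))
  E <- exp(S)
  atten <- E / rowSums(E)
  list(atten = atten, H = atten %*% H_L)
}

#' Linear reconstruction head
#'
#' @param H_prime `T x K` attended hidden states.
#' @param W_out `d x K` output weights.
#' @param b_out length-`d` bias.
#' @return `T x d` matrix of reconstructed attribute values.
#' @export
reconstruct <- function(H_prime, W_out, b_out) {
  sweep(as.matrix(H_prime) %*% t(W_out), 2L, b_out, "+")
}

#' Initialize the imputation network
#'
#' @param d number of attributes.
#' @param hidden decay-LSTM hidden size (default 64).
#' @param d_gcn graph-convolution features per node (default 1).
#' @param sigma GCN activation (default `"identity"`).
#' @param seed integer seed.
#' @return A list of class `imputer_model` holding all network parameters.
#' @export
imputer_init <- function(d, hidden = 64, d_gcn = 1, sigma = "identity",
                         seed = 1) {
  K <- hidden
  din <- K + d * d_gcn
  with_seed(seed, {
    sc <- 0.1
    structure(
      list(
        params = list(
          theta = rep(1, d_gcn),
          W_alpha = matrix(0, K, d),
          b_alpha = numeric(K),
          Wg = matrix(stats::rnorm(4 * K * din, sd = sc), 4 * K, din),
          bg = numeric(4 * K),
          w_attn = stats::rnorm(2 * K, sd = sc),
          W_out = matrix(stats::rnorm(d * K, sd = sc), d, K),
          b_out = numeric(d)
        ),
        d = d, hidden = K, d_gcn = d_gcn, sigma = sigma
      ),
      class = "imputer_model"
    )
  })
}

# ---- batched forward/backward ----------------------------------------------
# grp is a pack_windows() group (arrays B x L x d). Returns xhat and every
# cache needed for backprop.

imputer_forward_batch <- function(pars, A_hat, grp, sigma, hidden, d_gcn) {
  B <- grp$B; L <- grp$L; d <- dim(grp$X)[3]
  K <- hidden
  k <- d_gcn
  tAhat <- t(A_hat)
  node_idx <- rep(seq_len(d), each = k)
  feat_idx <- rep(seq_len(k), d)
  hg <- array(0, c(B, L, d * k))
  mixed_c <- array(0, c(B, L, d))
  pre_c <- array(0, c(B, L, d * k))
  alpha <- array(0, c(B, L, K))
  qpre <- array(0, c(B, L, K))
  H_L <- array(0, c(B, L, K))
  fs <- is_ <- os <- gs <- tss <- s_in <- h_in <- hp_l <- vector("list", L)
  h <- matrix(0, B, K)
  s <- matrix(0, B, K)
  tWa <- t(pars$W_alpha)
  tWg <- t(pars$Wg)
  for (t in seq_len(L)) {
    xt <- grp$X[, t, , drop = FALSE]; dim(xt) <- c(B, d)
    mixed <- xt %*% tAhat
    pre <- mixed[, node_idx, drop = FALSE] *
      matrix(pars$theta[feat_idx], B, d * k, byrow = TRUE)
    hg_t <- act_fun(sigma)(pre)
    mixed_c[, t, ] <- mixed
    pre_c[, t, ] <- pre
    hg[, t, ] <- hg_t

    dt <- grp$delta[, t, , drop = FALSE]; dim(dt) <- c(B, d)
    q <- sweep(dt %*% tWa, 2L, pars$b_alpha, "+")
    a_t <- exp(-pmax(q, 0))
    qpre[, t, ] <- q
    alpha[, t, ] <- a_t

    hp <- a_t * h
    z <- sweep(cbind(hp, hg_t) %*% tWg, 2L, pars$bg, "+")
    f <- sigmoid(z[, seq_len(K), drop = FALSE])
    i <- sigmoid(z[, K + seq_len(K), drop = FALSE])
    o <- sigmoid(z[, 2 * K + seq_len(K), drop = FALSE])
    g <- tanh(z[, 3 * K + seq_len(K), drop = FALSE])
    s_new <- f * s + i * g
    ts_ <- tanh(s_new)
    h_new <- o * ts_
    fs[[t]] <- f; is_[[t]] <- i; os[[t]] <- o; gs[[t]] <- g
    tss[[t]] <- ts_; s_in[[t]] <- s; h_in[[t]] <- h; hp_l[[t]] <- hp
    h <- h_new; s <- s_new
    H_L[, t, ] <- h
  }
  # attention + reconstruction per window
  xhat <- array(0, c(B, L, d))
  atten_l <- S_l <- Hp_l <- vector("list", B)
  w1 <- pars$w_attn[seq_len(K)]
  w2 <- pars$w_attn[K + seq_len(K)]
  for (b in seq_len(B)) {
    HLb <- matrix(H_L[b, , ], L, K)
    u <- drop(HLb %*% w1)
    v <- drop(HLb %*% w2)
    S <- tanh(outer(v, u, "+"))
    E <- exp(S)
    At <- E / rowSums(E)
    Hp <- At %*% HLb
    xhat[b, , ] <- sweep(Hp %*% t(pars$W_out), 2L, pars$b_out, "+")
    atten_l[[b]] <- At; S_l[[b]] <- S; Hp_l[[b]] <- Hp
  }
  list(xhat = xhat, hg = hg, mixed = mixed_c, pre = pre_c, alpha = alpha,
       qpre = qpre, H_L = H_L, f = fs, i = is_, o = os, g = gs, ts = tss,
       s_in = s_in, h_in = h_in, hp = hp_l, atten = atten_l, S = S_l,
       Hp = Hp_l, B = B, L = L, d = d, K = K, k = k)
}

imputer_backward_batch <- function(pars, A_hat, grp, cache, dxhat, sigma) {
  B <- cache$B; L <- cache$L; d <- cache$d; K <- cache$K; k <- cache$k
  node_idx <- rep(seq_len(d), each = k)
  grads <- par_zeros_like(pars)
  w1 <- pars$w_attn[seq_len(K)]
  w2 <- pars$w_attn[K + seq_len(K)]
  dH_L <- array(0, c(B, L, K))
  for (b in seq_len(B)) {
    dxb <- matrix(dxhat[b, , ], L, d)
    Hp <- cache$Hp[[b]]
    At <- cache$atten[[b]]
    S <- cache$S[[b]]
    HLb <- matrix(cache$H_L[b, , ], L, K)
    grads$W_out <- grads$W_out + crossprod(dxb, Hp)
    grads$b_out <- grads$b_out + colSums(dxb)
    dHp <- dxb %*% pars$W_out
    dAt <- tcrossprod(dHp, HLb)
    dHL <- crossprod(At, dHp)
    # softmax (rows) backward
    dS <- At * (dAt - rowSums(At * dAt))
    dE <- dS * (1 - S^2)
    du <- colSums(dE)
    dv <- rowSums(dE)
    grads$w_attn[seq_len(K)] <- grads$w_attn[seq_len(K)] +
      drop(crossprod(HLb, du))
    grads$w_attn[K + seq_len(K)] <- grads$w_attn[K + seq_len(K)] +
      drop(crossprod(HLb, dv))
    dHL <- dHL + tcrossprod(du, w1) + tcrossprod(dv, w2)
    dH_L[b, , ] <- dHL
  }
  # BPTT through the decay LSTM
  dhg <- array(0, c(B, L, d * k))
  dh <- matrix(0, B, K)
  ds <- matrix(0, B, K)
  dalpha_all <- array(0, c(B, L, K))
  for (t in L:1L) {
    dh <- dh + matrix(dH_L[, t, ], B, K)
    f <- cache$f[[t]]; i <- cache$i[[t]]; o <- cache$o[[t]]
    g <- cache$g[[t]]; ts_ <- cache$ts[[t]]
    do_ <- dh * ts_
    ds <- ds + dh * o * (1 - ts_^2)
    df <- ds * cache$s_in[[t]]
    di <- ds * g
    dg <- ds * i
    ds_prev <- ds * f
    dz <- cbind(df * f * (1 - f), di * i * (1 - i),
                do_ * o * (1 - o), dg * (1 - g^2))
    zin <- cbind(cache$hp[[t]], matrix(cache$hg[, t, ], B, d * k))
    grads$Wg <- grads$Wg + crossprod(dz, zin)
    grads$bg <- grads$bg + colSums(dz)
    dzin <- dz %*% pars$Wg
    dhp <- dzin[, seq_len(K), drop = FALSE]
    dhg[, t, ] <- dzin[, K + seq_len(d * k), drop = FALSE]
    a_t <- matrix(cache$alpha[, t, ], B, K)
    dalpha_all[, t, ] <- dhp * cache$h_in[[t]]
    dh <- dhp * a_t
    ds <- ds_prev
  }
  # decay parameters: alpha = exp(-max(q, 0))
  dq_all <- -dalpha_all * cache$alpha * (cache$qpre > 0)
  # B x L x * arrays flatten column-major the same way, so rows line up
  dflat <- matrix(grp$delta, B * L, d)
  dqm <- matrix(dq_all, B * L, K)
  grads$W_alpha <- grads$W_alpha + crossprod(dqm, dflat)
  grads$b_alpha <- grads$b_alpha + colSums(dqm)
  # GCN backward
  dpre <- dhg * act_grad(sigma, cache$pre)
  dpre_m <- matrix(dpre, B * L, d * k)
  mixed_m <- matrix(cache$mixed, B * L, d)
  for (ff in seq_len(k)) {
    cols <- (seq_len(d) - 1L) * k + ff
    grads$theta[ff] <- grads$theta[ff] +
      sum(dpre_m[, cols, drop = FALSE] * mixed_m)
  }
  # dL/dmixed[, node] = sum_f dpre[, node, f] * theta[f]
  dmixed <- matrix(0, B * L, d)
  for (ff in seq_len(k)) {
    cols <- (seq_len(d) - 1L) * k + ff
    dmixed <- dmixed + dpre_m[, cols, drop = FALSE] * pars$theta[ff]
  }
  X_m <- matrix(grp$X, B * L, d)
  dAhat <- crossprod(dmixed, X_m)
  list(grads = grads, dAhat = dAhat)
}
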