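# Internal numerical utilities shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Run `code` under a temporary RNG state seeded with `seed`.
# All stochastic operations in the package funnel through this so that no
# function touches the caller's global RNG stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream of child seeds from one master seed (keeps values < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- nested parameter lists -------------------------------------------------
# Model parameters are nested named lists whose leaves are numeric arrays.
# These helpers implement elementwise algebra over that structure, which is
# all Adam and the gradient checker need.

par_map <- function(f, x, ...) {
  if (is.list(x)) {
    rest <- list(...)
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (k in seq_along(x)) {
      out[[k]] <- do.call(par_map, c(list(f, x[[k]]), lapply(rest, `[[`, k)))
    }
    out
  } else {
    f(x, ...)
  }
}

par_zeros_like <- function(x) par_map(function(a) a * 0, x)

par_unlist <- function(x) unlist(x, use.names = FALSE)

par_relist <- function(flat, skeleton) {
  i <- 0L
  rebuild <- function(x) {
    if (is.list(x)) {
      lapply(x, rebuild)
    } else {
      n <- length(x)
      out <- x
      out[] <- flat[i + seq_len(n)]
      i <<- i + n
      out
    }
  }
  rebuild(skeleton)
}

# ---- Adam optimizer ---------------------------------------------------------

adam_init <- function(params) {
  list(m = par_zeros_like(params), v = par_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- par_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- par_map(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- par_map(
    function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
    params, state$m, state$v
  )
  list(params = params, state = state)
}

# Group soft-threshold: shrink the Euclidean norm of `g` by `tau`, returning
# exactly zero when the norm falls below tau (the proximal operator of the
# group-lasso penalty).
group_soft_threshold <- function(g, tau) {
  nrm <- sqrt(sum(g^2))
  if (nrm <= tau || nrm == 0) {
    g * 0
  } else {
    (1 - tau / nrm) * g
  }
}
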