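test_that("normalized_adjacency handles the canonical cases", {
  # zero adjacency: only self-loops, unit degrees
  expect_equal(normalized_adjacency(matrix(0, 3, 3)), diag(3))
  # symmetric single edge: degrees (2, 2), every entry 1/2
  expect_equal(normalized_adjacency(matrix(c(0, 1, 1, 0), 2, 2)),
               matrix(0.5, 2, 2))
  expect_error(normalized_adjacency(matrix(c(0, -1, 1, 0), 2, 2)),
               "nonnegative")
  expect_error(normalized_adjacency(matrix(0, 2, 3)), "square")
  # symmetric regular graphs keep unit row sums
  A <- matrix(1, 4, 4) - diag(4)
  expect_equal(rowSums(normalized_adjacency(A)), rep(1, 4))
})

test_that("normalized_adjacency matches a dense loop oracle", {
  oracle <- function(A) {
    d <- nrow(A)
    if (max(A) > 0) A <- A / max(A)
    At <- A + diag(d)
    r <- rowSums(At)
    out <- matrix(0, d, d)
    for (p in seq_len(d)) {
      for (q in seq_len(d)) out[p, q] <- At[p, q] / sqrt(r[p] * r[q])
    }
    out
  }
  withr::with_seed(51, {
    for (rep in 1:120) {
      d <- sample(2:5, 1)
      A <- matrix(runif(d * d, 0, 5), d, d)
      expect_equal(normalized_adjacency(A), oracle(A), tolerance = 1e-9)
    }
  })
})

test_that("gcn_forward mixes node signals then applies the feature map", {
  X <- matrix(rnorm(8), 4, 2)
  # identity pipeline
  expect_equal(gcn_forward(X, diag(2), theta = 1, sigma = "identity"), X)
  # uniform mixing: both outputs are the scaled timestep mean
  Ah <- matrix(0.5, 2, 2)
  got <- gcn_forward(X, Ah, theta = 1)
  want <- cbind(0.5 * rowSums(X), 0.5 * rowSums(X))
  expect_equal(got, want)
  expect_error(gcn_forward(X, diag(3)), "match")
})

test_that("gcn_forward agrees with an explicit-loop oracle", {
  oracle <- function(X, Ah, theta, sig) {
    n <- nrow(X); d <- ncol(X); k <- length(theta)
    out <- matrix(0, n, d * k)
    f <- switch(sig, identity = function(z) z, relu = function(z) max(z, 0),
                tanh = tanh)
    for (t in seq_len(n)) {
      mixed <- as.numeric(Ah %*% X[t, ])
      for (node in seq_len(d)) {
        for (ff in seq_len(k)) {
          out[t, (node - 1) * k + ff] <- f(mixed[node] * theta[ff])
        }
      }
    }
    out
  }
  withr::with_seed(52, {
    for (rep in 1:120) {
      n <- sample(2:10, 1); d <- sample(2:4, 1)
      k <- sample(1:2, 1)
      sig <- sample(c("identity", "relu", "tanh"), 1)
      X <- matrix(rnorm(n * d), n, d)
      Ah <- normalized_adjacency(matrix(runif(d * d), d, d))
      th <- rnorm(k)
      expect_equal(gcn_forward(X, Ah, th, sig), oracle(X, Ah, th, sig),
                   tolerance = 1e-9)
    }
  })
})

test_that("decay_vector lies in (0,1] and hits its closed forms", {
  d <- 3; K <- 2
  expect_equal(decay_vector(rep(5, d), matrix(0, K, d), numeric(K)),
               rep(1, K))
  # scalar case tuned to ln 2 gives exactly 1/2
  expect_equal(decay_vector(1, matrix(log(2), 1, 1), 0), 0.5)
  withr::with_seed(53, {
    for (rep in 1:50) {
      a <- decay_vector(runif(d, 0, 10), matrix(rnorm(K * d), K, d), rnorm(K))
      expect_true(all(a > 0 & a <= 1))
    }
  })
})

test_that("decay is non-increasing in each lag for nonnegative weights", {
  withr::with_seed(54, {
    d <- 4; K <- 3
    W <- matrix(runif(K * d), K, d)
    b <- rnorm(K)
    delta <- runif(d, 0, 5)
    a0 <- decay_vector(delta, W, b)
    for (j in seq_len(d)) {
      bumped <- delta
      bumped[j] <- bumped[j] + 1
      expect_true(all(decay_vector(bumped, W, b) <= a0 + 1e-12))
    }
  })
})

test_that("decay_lstm_step reduces to a plain LSTM at alpha = 1", {
  withr::with_seed(55, {
    K <- 3; din <- 5
    p <- list(Wg = matrix(rnorm(4 * K * (K + din)), 4 * K, K + din),
              bg = rnorm(4 * K))
    h <- rnorm(K); s <- rnorm(K); hg <- rnorm(din)
    got <- decay_lstm_step(h, s, hg, rep(1, K), p)
    # plain LSTM on the concatenated input [h; hg]
    z <- drop(p$Wg %*% c(h, hg)) + p$bg
    sig <- function(x) 1 / (1 + exp(-x))
    f <- sig(z[1:K]); i <- sig(z[K + 1:K]); o <- sig(z[2 * K + 1:K])
    g <- tanh(z[3 * K + 1:K])
    expect_equal(got$s, f * s + i * g, tolerance = 1e-12)
    expect_equal(got$h, o * tanh(f * s + i * g), tolerance = 1e-12)
    # alpha = 0 erases the hidden-state contribution entirely
    a <- decay_lstm_step(h, s, hg, rep(0, K), p)
    b <- decay_lstm_step(h + 100, s, hg, rep(0, K), p)
    expect_equal(a$h, b$h)
    expect_equal(a$s, b$s)
    expect_error(decay_lstm_step(h, s[1:2], hg, rep(1, K), p), "inconsistent")
  })
})

test_that("decay_lstm_step matches a scalar-loop oracle", {
  oracle <- function(h, s, hg, a, p) {
    K <- length(h)
    zin <- c(a * h, hg)
    sig <- function(x) 1 / (1 + exp(-x))
    hn <- sn <- numeric(K)
    for (u in seq_len(K)) {
      f <- sig(sum(p$Wg[u, ] * zin) + p$bg[u])
      i <- sig(sum(p$Wg[K + u, ] * zin) + p$bg[K + u])
      o <- sig(sum(p$Wg[2 * K + u, ] * zin) + p$bg[2 * K + u])
      g <- tanh(sum(p$Wg[3 * K + u, ] * zin) + p$bg[3 * K + u])
      sn[u] <- f * s[u] + i * g
      hn[u] <- o * tanh(sn[u])
    }
    list(h = hn, s = sn)
  }
  withr::with_seed(56, {
    for (rep in 1:120) {
      K <- sample(1:4, 1); din <- sample(1:4, 1)
      p <- list(Wg = matrix(rnorm(4 * K * (K + din)), 4 * K, K + din),
                bg = rnorm(4 * K))
      h <- rnorm(K); s <- rnorm(K); hg <- rnorm(din)
      a <- runif(K)
      got <- decay_lstm_step(h, s, hg, a, p)
      want <- oracle(h, s, hg, a, p)
      expect_equal(got$h, want$h, tolerance = 1e-9)
      expect_equal(got$s, want$s, tolerance = 1e-9)
    }
  })
})

test_that("temporal attention rows are proper softmax weights", {
  withr::with_seed(57, {
    K <- 3
    H <- matrix(rnorm(5 * K), 5, K)
    # single timestep: weight 1, representation unchanged
    one <- temporal_attention(H[1, , drop = FALSE], rnorm(2 * K))
    expect_equal(one$atten, matrix(1, 1, 1))
    expect_equal(one$H, H[1, , drop = FALSE])
    # zero weights: uniform attention, rows become the column mean
    unif <- temporal_attention(H, numeric(2 * K))
    expect_equal(unif$atten, matrix(1 / 5, 5, 5))
    for (t in 1:5) expect_equal(unif$H[t, ], colMeans(H), tolerance = 1e-12)
    # random weights: rows sum to one, entries in (0, 1)
    for (rep in 1:30) {
      w <- rnorm(2 * K)
      at <- temporal_attention(H, w)$atten
      expect_equal(rowSums(at), rep(1, 5), tolerance = 1e-9)
      expect_true(all(at > 0 & at < 1))
    }
  })
})

test_that("reconstruct is the affine output head", {
  withr::with_seed(58, {
    H <- matrix(rnorm(12), 4, 3)
    b <- c(1, -2)
    expect_equal(reconstruct(H, matrix(0, 2, 3), b),
                 matrix(rep(b, each = 4), 4, 2))
    W <- rbind(c(1, 0, 0), c(0, 1, 0))
    expect_equal(reconstruct(H, W, c(0, 0)), H[, 1:2])
    # affine in H' for fixed bias
    H2 <- matrix(rnorm(12), 4, 3)
    a <- 0.3
    Wr <- matrix(rnorm(6), 2, 3)
    expect_equal(
      reconstruct(a * H + (1 - a) * H2, Wr, b),
      a * reconstruct(H, Wr, b) + (1 - a) * reconstruct(H2, Wr, b),
      tolerance = 1e-12
    )
  })
})

test_that("impute_missing preserves observed cells and completes the rest", {
  ds <- small_dataset(n = 30, d = 3, p = 0.3)
  fit <- train_imputer(ds, hidden = 6, granger_hidden = 2, epochs = 3,
                       window_length = 10, seed = 9)
  out <- impute_missing(fit, ds, denormalize = FALSE)
  obs <- ds$mask == 1L
  expect_identical(out$values[obs], ds$values[obs])
  expect_false(anyNA(out$values))
  expect_true(all(out$mask == 1L))
  # fully observed input passes through exactly
  full <- ts_dataset(matrix(runif(30), 10, 3))
  expect_identical(impute_missing(fit, full, denormalize = FALSE)$values,
                   full$values)
  # idempotent on its own completed output
  again <- impute_missing(fit, out, denormalize = FALSE)
  expect_identical(again$values, out$values)
  # attribute-count mismatch is rejected
  bad <- ts_dataset(matrix(runif(20), 10, 2))
  expect_error(impute_missing(fit, bad), "attributes")
})

test_that("imputations are finite for random models on random input", {
  withr::with_seed(59, {
    for (rep in 1:5) {
      ds <- small_dataset(n = 25, d = 3, p = 0.4, seed = rep)
      fit <- train_imputer(ds, hidden = 4, granger_hidden = 2, epochs = 2,
                           window_length = 8, seed = rep)
      out <- impute_missing(fit, ds, denormalize = FALSE)
      expect_true(all(is.finite(out$values)))
    }
  })
})

test_that("a trailing unwindowed timestamp still gets imputed", {
  sim <- simulate_var(d = 3, n = 21, parents_per_node = 1, seed = 2)
  vals <- sim$dataset$values
  vals[21, 2] <- NA
  vals[5, 1] <- NA
  ds <- ts_dataset(vals)
  ds <- apply_scaler(ds, fit_scaler(ds))
  fit <- train_imputer(ds, hidden = 4, granger_hidden = 2, epochs = 2,
                       window_length = 10, seed = 3)
  out <- impute_missing(fit, ds, denormalize = FALSE)
  expect_false(anyNA(out$values))
})
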