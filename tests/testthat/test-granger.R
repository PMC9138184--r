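test_that("lstm_cell matches hand-derived special cases", {
  H <- 3; d <- 2
  zero <- list(W = matrix(0, 4 * H, d), U = matrix(0, 4 * H, H),
               b = numeric(4 * H))
  # all-zero parameters and states: candidate tanh(0) = 0 kills everything
  out <- lstm_cell(c(1, -2), numeric(H), numeric(H), zero)
  expect_equal(out$h, numeric(H))
  expect_equal(out$c, numeric(H))
  # zero parameters, nonzero cell state: every gate is sigma(0) = 1/2
  cprev <- c(0.4, -1, 2)
  out <- lstm_cell(c(1, -2), numeric(H), cprev, zero)
  expect_equal(out$c, 0.5 * cprev)
  expect_equal(out$h, 0.5 * tanh(0.5 * cprev))
  expect_error(lstm_cell(c(1, 2, 3), numeric(H), numeric(H), zero),
               "inconsistent")
})

test_that("lstm_cell agrees with a scalar-loop oracle on random instances", {
  cell_oracle <- function(x, h, cc, p) {
    H <- length(h)
    hn <- cn <- numeric(H)
    for (u in seq_len(H)) {
      zf <- sum(p$W[u, ] * x) + sum(p$U[u, ] * h) + p$b[u]
      zi <- sum(p$W[H + u, ] * x) + sum(p$U[H + u, ] * h) + p$b[H + u]
      zo <- sum(p$W[2 * H + u, ] * x) + sum(p$U[2 * H + u, ] * h) +
        p$b[2 * H + u]
      zg <- sum(p$W[3 * H + u, ] * x) + sum(p$U[3 * H + u, ] * h) +
        p$b[3 * H + u]
      cn[u] <- 1 / (1 + exp(-zf)) * cc[u] + 1 / (1 + exp(-zi)) * tanh(zg)
      hn[u] <- 1 / (1 + exp(-zo)) * tanh(cn[u])
    }
    list(h = hn, c = cn)
  }
  withr::with_seed(21, {
    for (rep in 1:120) {
      H <- sample(1:4, 1); d <- sample(1:3, 1)
      p <- list(W = matrix(rnorm(4 * H * d), 4 * H, d),
                U = matrix(rnorm(4 * H * H), 4 * H, H),
                b = rnorm(4 * H))
      x <- rnorm(d); h <- rnorm(H); cc <- rnorm(H)
      got <- lstm_cell(x, h, cc, p)
      want <- cell_oracle(x, h, cc, p)
      expect_equal(got$h, want$h, tolerance = 1e-9)
      expect_equal(got$c, want$c, tolerance = 1e-9)
    }
  })
})

test_that("predict_series is one-step-ahead and strictly causal", {
  m <- granger_init(2, hidden = 1, seed = 8)
  X <- matrix(rnorm(12), 6, 2)
  pred <- predict_series(m, 1, X)
  expect_true(is.na(pred[1]))
  # zero-parameter model predicts the output bias everywhere
  z <- m
  z$targets[[1]] <- lapply(z$targets[[1]], function(x) x * 0)
  z$targets[[1]]$c0 <- 0.37
  expect_equal(predict_series(z, 1, X)[-1], rep(0.37, 5))
  # perturbing x_t must not change the prediction at t
  X2 <- X
  X2[4, ] <- X2[4, ] + 100
  expect_equal(predict_series(m, 1, X)[4], predict_series(m, 1, X2)[4])
  expect_error(predict_series(m, 1, X[1, , drop = FALSE]), "at least 2")
})

test_that("predict_series matches a hand-unrolled two-step computation", {
  H <- 1; d <- 2
  p <- list(W = matrix(c(0.1, -0.2, 0.3, 0.05, -0.1, 0.2, 0.15, -0.05),
                       4, 2),
            U = matrix(c(0.2, -0.3, 0.1, 0.25), 4, 1),
            b = c(0.01, -0.02, 0.03, 0.04),
            v = 0.5, c0 = -0.1)
  m <- structure(list(targets = list(p, p), hidden = 1, lambda = 0, d = 2),
                 class = "granger_model")
  X <- matrix(c(0.3, -0.4, 0.6, 0.2, -0.5, 0.1), 3, 2, byrow = TRUE)
  s1 <- lstm_cell(X[1, ], 0, 0, p)
  s2 <- lstm_cell(X[2, ], s1$h, s1$c, p)
  want <- c(NA, 0.5 * s1$h - 0.1, 0.5 * s2$h - 0.1)
  expect_equal(predict_series(m, 1, X), want, tolerance = 1e-12)
})

test_that("group_penalty is the sum of column-group norms", {
  expect_equal(group_penalty(matrix(0, 8, 3)), 0)
  W <- matrix(0, 8, 3)
  W[c(2, 5), 2] <- c(3, 4)
  expect_equal(group_penalty(W), 5)
  withr::with_seed(2, {
    W <- matrix(rnorm(24), 8, 3)
    expect_equal(group_penalty(-2.5 * W), 2.5 * group_penalty(W))
  })
})

test_that("granger_loss is the masked SSE plus lambda * penalty", {
  d <- 2
  m <- granger_init(d, hidden = 2, seed = 1)
  # zero model, lambda = 0: residual is the observed target itself
  m$targets <- lapply(m$targets, function(p) lapply(p, function(x) x * 0))
  w <- ts_dataset(matrix(c(1, 2, NA, NA), 2, 2))
  expect_equal(granger_loss(m, w, 0), 4)  # only x[2,1] = 2 is scored
  # linearity in lambda
  m2 <- granger_init(d, hidden = 2, seed = 3)
  pen <- sum(vapply(m2$targets, function(p) group_penalty(p$W), 0))
  expect_equal(granger_loss(m2, w, 1) - granger_loss(m2, w, 0), pen)
  expect_error(granger_loss(m2, w, -1), "nonnegative")
})

test_that("extract_adjacency reads only the input weight groups", {
  d <- 3
  m <- granger_init(d, hidden = 2, seed = 1)
  m$targets <- lapply(m$targets, function(p) lapply(p, function(x) x * 0))
  expect_equal(extract_adjacency(m), matrix(0, d, d))
  m$targets[[2]]$W[c(1, 4), 3] <- c(1, 2)
  A <- extract_adjacency(m)
  expect_equal(A[3, 2], 5)
  expect_equal(sum(A), 5)
  # invariant to recurrent weights and biases
  m$targets[[2]]$U[] <- 100
  m$targets[[2]]$b[] <- -3
  expect_equal(extract_adjacency(m), A)
  # nonnegative for arbitrary parameters
  withr::with_seed(5, {
    m3 <- granger_init(d, hidden = 3, seed = 11)
    expect_true(all(extract_adjacency(m3) >= 0))
  })
})

test_that("group soft-threshold matches the closed-form proximal operator", {
  withr::with_seed(14, {
    for (rep in 1:50) {
      g <- rnorm(sample(1:12, 1))
      tau <- runif(1, 0, 2)
      want <- max(0, 1 - tau / sqrt(sum(g^2))) * g
      expect_equal(cgimpute:::group_soft_threshold(g, tau), want,
                   tolerance = 1e-12)
    }
    expect_equal(cgimpute:::group_soft_threshold(numeric(3), 0.5), numeric(3))
  })
})

test_that("fit_granger is seeded-deterministic and large lambda zeroes A", {
  ds <- small_dataset(n = 40, d = 3)
  f1 <- fit_granger(ds, hidden = 4, epochs = 5, window_length = 10, seed = 2)
  f2 <- fit_granger(ds, hidden = 4, epochs = 5, window_length = 10, seed = 2)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$A, f2$A)
  # a huge penalty drives every input group exactly to zero
  fz <- fit_granger(ds, hidden = 4, lambda = 1e6, lr = 1e-2, epochs = 3,
                    window_length = 10, seed = 2)
  expect_equal(fz$A, matrix(0, 3, 3))
})

test_that("fitting ranks a true lagged edge above its reverse", {
  # attribute 2 = 0.9 * lag-1 of attribute 1 + small noise
  withr::with_seed(31, {
    n <- 400
    x1 <- as.numeric(arima.sim(list(ar = 0.5), n))
    x2 <- 0.9 * dplyr::lag(x1, 1) + rnorm(n, sd = 0.1)
    vals <- cbind(x1, x2)[-1, ]
  })
  ds <- ts_dataset(vals)
  ds <- apply_scaler(ds, fit_scaler(ds))
  fit <- fit_granger(ds, hidden = 8, lambda = 0.05, lr = 1e-2, epochs = 60,
                     window_length = 40, seed = 6)
  expect_gt(fit$A[1, 2], fit$A[2, 1])
})

test_that("adjacency csv round-trips", {
  A <- matrix(runif(9), 3, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_adjacency(A, path, attribute_names = c("a", "b", "c"))
  back <- read_adjacency(path)
  expect_equal(unname(back), A, tolerance = 1e-12)
  expect_equal(rownames(back), c("a", "b", "c"))
})
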