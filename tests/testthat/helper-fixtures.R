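# Shared fixtures, built in code.

# The worked 3 x 5 example matrix with "/" (absent) entries.
example_matrix <- function() {
  matrix(
    c(5, NA, NA, NA, 18,
      12, 32, 9, NA, 76,
      2, NA, 24, NA, 47),
    nrow = 3, byrow = TRUE
  )
}

example_mask <- function() {
  matrix(
    c(1L, 0L, 0L, 0L, 1L,
      1L, 1L, 1L, 0L, 1L,
      1L, 0L, 1L, 0L, 1L),
    nrow = 3, byrow = TRUE
  )
}

# A small normalized dataset with scattered missingness.
small_dataset <- function(n = 20, d = 3, p = 0.2, seed = 5) {
  sim <- simulate_var(d = d, n = n, parents_per_node = 1, seed = seed)
  drop <- inject_missing(sim$dataset, p, seed + 1)
  apply_scaler(drop$corrupted, fit_scaler(drop$corrupted))
}

# Tiny models with perturbed (non-symmetric) parameters for numeric checks.
tiny_models <- function(d = 3, H = 2, K = 3, seed = 4) {
  withr::with_seed(seed, {
    gm <- granger_init(d, hidden = H, lambda = 0.05, seed = seed)
    gm$targets <- par_jitter(gm$targets, 0.05)
    im <- imputer_init(d, hidden = K, d_gcn = 1, seed = seed + 1)
    im$params <- par_jitter(im$params, 0.05)
    list(granger = gm, imputer = im)
  })
}

# jitter every leaf of a nested parameter list (assumes RNG already seeded)
par_jitter <- function(x, sd) {
  if (is.list(x)) {
    lapply(x, par_jitter, sd = sd)
  } else {
    x + stats::rnorm(length(x), sd = sd)
  }
}
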