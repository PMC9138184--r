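# Canonical data model for incomplete multivariate time series: values,
# binary observation mask, timestamps, time-lag matrices, min-max scaling,
# windowing and evaluation-drop injection.

#' Construct a multivariate time-series dataset
#'
#' Bundles an `n x d` value matrix (with `NA` marking absent entries), the
#' binary observation mask derived from it, a strictly increasing timestamp
#' vector and attribute names into a `ts_dataset` object. The mask is the
#' single source of truth for missingness: `mask[t, j] == 1` exactly when
#' `values[t, j]` is observed.
#'
#' @param values numeric matrix, one row per timestamp, one column per
#'   attribute; `NA` marks an absent observation.
#' @param timestamps strictly increasing numeric vector of length `nrow(values)`
#'   (arbitrary time units). Defaults to the row index with unit spacing.
#' @param attribute_names character vector of length `ncol(values)`.
#' @return An object of class `ts_dataset` with elements `values`, `mask`,
#'   `timestamps`, `attribute_names`.
#' @examples
#' x <- matrix(c(5, NA, 18, 12, 32, 76), nrow = 2, byrow = TRUE)
#' ds <- ts_dataset(x)
#' ds$mask
#' @export
ts_dataset <- function(values, timestamps = NULL, attribute_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("`values` must have at least one row and one column", call. = FALSE)
  }
  n <- nrow(values)
  d <- ncol(values)
  timestamps <- timestamps %||% seq_len(n)
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) != n) {
    stop("`timestamps` must have one entry per row of `values`", call. = FALSE)
  }
  if (n > 1L && any(diff(timestamps) <= 0)) {
    stop("`timestamps` must be strictly increasing", call. = FALSE)
  }
  attribute_names <- attribute_names %||% colnames(values) %||%
    paste0("V", seq_len(d))
  if (length(attribute_names) != d) {
    stop("`attribute_names` must have one entry per column", call. = FALSE)
  }
  dimnames(values) <- list(NULL, attribute_names)
  structure(
    list(
      values = values,
      mask = compute_mask(values),
      timestamps = timestamps,
      attribute_names = as.character(attribute_names)
    ),
    class = "ts_dataset"
  )
}

#' @export
print.ts_dataset <- function(x, ...) {
  obs <- sum(x$mask)
  cat(sprintf(
    "<ts_dataset: %d timestamps x %d attributes, %.1f%% observed>\n",
    nrow(x$values), ncol(x$values), 100 * obs / length(x$mask)
  ))
  invisible(x)
}

#' @export
dim.ts_dataset <- function(x) dim(x$values)

#' Create a `ts_dataset` from a wide data frame
#'
#' Accepts the wide delimited layout used throughout the package: one row per
#' timestamp, one column per attribute, empty cells (`NA`) meaning missing,
#' and an optional timestamp column (numeric or parseable date-time).
#'
#' @param df a data frame, one row per timestamp.
#' @param timestamp_col name of the timestamp column, or `NULL` if absent
#'   (row index with unit spacing is used). Default `"timestamp"` when such a
#'   column exists.
#' @return A [ts_dataset()].
#' @export
as_ts_dataset <- function(df, timestamp_col = NULL) {
  df <- as.data.frame(df)
  if (is.null(timestamp_col) && "timestamp" %in% names(df)) {
    timestamp_col <- "timestamp"
  }
  ts <- NULL
  if (!is.null(timestamp_col)) {
    if (!timestamp_col %in% names(df)) {
      stop("timestamp column `", timestamp_col, "` not found", call. = FALSE)
    }
    raw <- df[[timestamp_col]]
    ts <- if (inherits(raw, c("POSIXct", "POSIXt", "Date"))) {
      as.numeric(raw)
    } else if (is.character(raw)) {
      parsed <- suppressWarnings(as.numeric(raw))
      if (anyNA(parsed)) as.numeric(as.POSIXct(raw, tz = "UTC")) else parsed
    } else {
      as.numeric(raw)
    }
    df[[timestamp_col]] <- NULL
  }
  ts_dataset(as.matrix(df), timestamps = ts, attribute_names = names(df))
}

#' Convert a `ts_dataset` to a wide tibble
#'
#' @param ds a [ts_dataset()].
#' @return A tibble with a `timestamp` column followed by one column per
#'   attribute; absent entries are `NA`.
#' @export
ts_as_tibble <- function(ds) {
  stopifnot(inherits(ds, "ts_dataset"))
  vals <- ds$values
  vals[ds$mask == 0L] <- NA_real_
  out <- tibble::as_tibble(as.data.frame(vals))
  dplyr::bind_cols(tibble::tibble(timestamp = ds$timestamps), out)
}

#' Binary observation mask of a value matrix
#'
#' Returns the indicator matrix that is 1 where an entry is observed and 0
#' where it is absent (`NA`).
#'
#' @param values numeric matrix with `NA` marking absent entries.
#' @return Integer matrix of the same shape with entries in `{0, 1}`.
#' @examples
#' compute_mask(matrix(c(1, NA, 3, 4), 2))
#' @export
compute_mask <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("`values` must be non-empty", call. = FALSE)
  }
  m <- ifelse(is.na(values), 0L, 1L)
  storage.mode(m) <- "integer"
  dimnames(m) <- dimnames(values)
  m
}

#' Time-lag matrix: elapsed time since the last observation
#'
#' For each attribute `j` and timestamp `t`, `delta[t, j]` is the time elapsed
#' since attribute `j` was last observed, computed by the per-attribute
#' recursion: `delta[1, j] = 0`; for `t > 1`, `delta[t, j] =
#' s_t - s_{t-1}` when the attribute was observed at `t - 1`, and
#' `s_t - s_{t-1} + delta[t-1, j]` when it was not. Gaps therefore accumulate
#' across consecutive missing steps.
#'
#' @param timestamps strictly increasing numeric vector of length `n`.
#' @param mask `n x d` binary observation mask.
#' @return `n x d` nonnegative numeric matrix.
#' @examples
#' compute_time_lag(0:3, matrix(c(1, 0, 0, 1), ncol = 1))
#' @export
compute_time_lag <- function(timestamps, mask) {
  mask <- as.matrix(mask)
  n <- nrow(mask)
  d <- ncol(mask)
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) != n) {
    stop("`timestamps` length must match rows of `mask`", call. = FALSE)
  }
  if (n > 1L && any(diff(timestamps) <= 0)) {
    stop("`timestamps` must be strictly increasing", call. = FALSE)
  }
  delta <- matrix(0, n, d, dimnames = dimnames(mask))
  if (n > 1L) {
    gaps <- diff(timestamps)
    for (t in 2:n) {
      carried <- ifelse(mask[t - 1L, ] == 1L, 0, delta[t - 1L, ])
      delta[t, ] <- gaps[t - 1L] + carried
    }
  }
  delta
}

#' Fit a per-attribute min-max scaler over observed entries
#'
#' Computes, for each attribute, the minimum and maximum over observed entries
#' only. [apply_scaler()] then maps observed values to `[0, 1]`; a constant
#' attribute maps to 0 (degenerate range).
#'
#' @param ds a [ts_dataset()].
#' @return An object of class `ts_scaler` with numeric vectors `min`, `max`.
#' @export
fit_scaler <- function(ds) {
  stopifnot(inherits(ds, "ts_dataset"))
  d <- ncol(ds$values)
  mins <- maxs <- numeric(d)
  for (j in seq_len(d)) {
    obs <- ds$values[ds$mask[, j] == 1L, j]
    if (length(obs) == 0L) {
      stop("attribute `", ds$attribute_names[j],
           "` has no observed entries; cannot fit scaler", call. = FALSE)
    }
    mins[j] <- min(obs)
    maxs[j] <- max(obs)
  }
  structure(
    list(min = mins, max = maxs, attribute_names = ds$attribute_names),
    class = "ts_scaler"
  )
}

#' Apply a fitted min-max scaler
#'
#' @param ds a [ts_dataset()].
#' @param scaler a [fit_scaler()] result.
#' @return The dataset with observed entries mapped to `[0, 1]`; absent
#'   entries and the mask are unchanged.
#' @export
apply_scaler <- function(ds, scaler) {
  stopifnot(inherits(ds, "ts_dataset"), inherits(scaler, "ts_scaler"))
  rng <- scaler$max - scaler$min
  vals <- ds$values
  for (j in seq_len(ncol(vals))) {
    if (rng[j] > 0) {
      vals[, j] <- (vals[, j] - scaler$min[j]) / rng[j]
    } else {
      vals[, j] <- ifelse(is.na(vals[, j]), NA_real_, 0)
    }
  }
  out <- ds
  out$values <- vals
  out
}

#' Invert a fitted min-max scaler
#'
#' @inheritParams apply_scaler
#' @return The dataset mapped back to the original units. Attributes that were
#'   constant at fit time are restored to that constant.
#' @export
invert_scaler <- function(ds, scaler) {
  stopifnot(inherits(ds, "ts_dataset"), inherits(scaler, "ts_scaler"))
  rng <- scaler$max - scaler$min
  vals <- ds$values
  for (j in seq_len(ncol(vals))) {
    if (rng[j] > 0) {
      vals[, j] <- vals[, j] * rng[j] + scaler$min[j]
    } else {
      vals[, j] <- ifelse(is.na(vals[, j]), NA_real_, scaler$min[j])
    }
  }
  out <- ds
  out$values <- vals
  out
}

#' Split a dataset into consecutive non-overlapping windows
#'
#' Cuts the series into consecutive windows of `window_length` timestamps. A
#' final partial window is kept when it has at least two timestamps and
#' dropped otherwise. Each window carries its own mask and timestamps; its
#' time-lag matrix restarts at zero within the window.
#'
#' @param ds a [ts_dataset()].
#' @param window_length integer window length, at least 2.
#' @return A list of [ts_dataset()] windows.
#' @export
ts_segment <- function(ds, window_length) {
  stopifnot(inherits(ds, "ts_dataset"))
  if (!is.numeric(window_length) || window_length < 2) {
    stop("`window_length` must be at least 2", call. = FALSE)
  }
  window_length <- as.integer(window_length)
  n <- nrow(ds$values)
  starts <- seq.int(1L, n, by = window_length)
  out <- list()
  for (s in starts) {
    e <- min(s + window_length - 1L, n)
    if (e - s + 1L < 2L) next
    out[[length(out) + 1L]] <- ts_dataset(
      ds$values[s:e, , drop = FALSE],
      timestamps = ds$timestamps[s:e],
      attribute_names = ds$attribute_names
    )
  }
  out
}

#' Inject random evaluation drops (MCAR)
#'
#' Removes exactly `round(p * n_observed)` currently observed entries, chosen
#' uniformly without replacement under `seed`, recording them in an
#' evaluation mask. The corrupted mask equals the original mask minus the
#' evaluation mask, so ground truth exists for every scored entry.
#'
#' @param ds a [ts_dataset()].
#' @param p drop fraction in `[0, 1)`.
#' @param seed integer seed controlling the drop positions.
#' @return A list with elements `corrupted` (a [ts_dataset()]) and
#'   `eval_mask` (integer matrix marking dropped entries).
#' @export
inject_missing <- function(ds, p, seed) {
  stopifnot(inherits(ds, "ts_dataset"))
  if (!is.numeric(p) || p < 0 || p >= 1) {
    stop("`p` must lie in [0, 1)", call. = FALSE)
  }
  obs_idx <- which(ds$mask == 1L)
  n_drop <- round(p * length(obs_idx))
  eval_mask <- matrix(0L, nrow(ds$mask), ncol(ds$mask),
                      dimnames = dimnames(ds$mask))
  if (n_drop > 0L) {
    drop_idx <- with_seed(seed, sample(obs_idx, n_drop))
    eval_mask[drop_idx] <- 1L
  }
  vals <- ds$values
  vals[eval_mask == 1L] <- NA_real_
  corrupted <- ts_dataset(vals, ds$timestamps, ds$attribute_names)
  list(corrupted = corrupted, eval_mask = eval_mask)
}

# Zero-fill absent entries (post-normalization convention used by the
# network modules; the mask and time-lag matrix carry the missingness).
zero_fill <- function(ds) {
  vals <- ds$values
  vals[ds$mask == 0L] <- 0
  vals
}

#' Read a wide delimited time-series table
#'
#' @param path path to a comma-separated file with a header row of attribute
#'   names, optionally a `timestamp` column, and empty cells for missing
#'   entries.
#' @return A [ts_dataset()].
#' @export
read_timeseries <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_ts_dataset(df)
}

#' Write a `ts_dataset` as a wide delimited table
#'
#' @param ds a [ts_dataset()].
#' @param path output path; absent entries become empty cells.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ds, path) {
  readr::write_csv(ts_as_tibble(ds), path, na = "", progress = FALSE)
  invisible(path)
}
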