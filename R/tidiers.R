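# Broom-style accessors and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted Granger model into an edge list
#'
#' @param x a [fit_granger()] result.
#' @param ... unused.
#' @return A tibble with columns `from`, `to`, `strength` (the adjacency
#'   entry, squared Frobenius norm of the input-weight group), one row per
#'   directed attribute pair.
#' @export
tidy.granger_fit <- function(x, ...) {
  nms <- x$attribute_names
  d <- ncol(x$A)
  tibble::tibble(
    from = rep(nms, times = d),
    to = rep(nms, each = d),
    strength = as.vector(x$A)
  )
}

#' @rdname tidy.granger_fit
#' @export
glance.granger_fit <- function(x, ...) {
  tibble::tibble(
    d = ncol(x$A),
    hidden = x$config$hidden,
    lambda = x$config$lambda,
    epochs = x$config$epochs,
    final_loss = x$history$loss[nrow(x$history)],
    n_nonzero_edges = sum(x$A > 0) - sum(diag(x$A) > 0)
  )
}

#' Plot a fitted Granger adjacency as a heatmap
#'
#' @param object a `granger_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.granger_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$to, levels = object$attribute_names),
    y = factor(.data$from, levels = rev(object$attribute_names)),
    fill = .data$strength
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "effect (target)", y = "cause (source)",
                  fill = "strength",
                  title = "Granger causal adjacency") +
    ggplot2::theme_minimal()
}

#' Tidy a trained imputation model's loss history
#'
#' @param x a [train_imputer()] result.
#' @param ... unused.
#' @return A long tibble with columns `epoch`, `component`
#'   (`l_ng`/`l_rec`/`l_tv`/`total`) and `loss`.
#' @export
tidy.cgcn_fit <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch",
                      names_to = "component", values_to = "loss")
}

#' @rdname tidy.cgcn_fit
#' @export
glance.cgcn_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    d = length(x$attribute_names),
    hidden = x$config$hidden,
    granger_hidden = x$config$granger_hidden,
    epochs = x$config$epochs,
    joint_causality = x$config$joint_causality,
    final_l_rec = h$l_rec[nrow(h)],
    final_total = h$total[nrow(h)]
  )
}

#' Plot training loss curves
#'
#' @param object a `cgcn_fit`.
#' @param ... unused.
#' @return A ggplot object with one facet per loss component (log scale).
#' @export
autoplot.cgcn_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(title = "Training loss components") +
    ggplot2::theme_minimal()
}

#' Plot a missing-rate sweep report
#'
#' @param object an `eval_report` from [sweep_missing_rates()].
#' @param metric `"rmse"` (default) or `"mae"`.
#' @param ... unused.
#' @return A ggplot object: error versus missing rate, one line per method.
#' @export
autoplot.eval_report <- function(object, metric = c("rmse", "mae"), ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object, ggplot2::aes(
    .data$missing_rate, .data[[metric]], colour = .data$method
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "missing rate", y = toupper(metric),
                  title = "Imputation error by missing rate") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
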