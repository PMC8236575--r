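layout_decode <- function(layout, dims) {
  per_channel <- sum(layout$dims)
  feature_of <- rep(layout$feature, layout$dims)
  component_of <- unlist(lapply(layout$dims, seq_len))
  within <- (dims - 1L) %% per_channel + 1L
  tibble::tibble(
    dim = as.integer(dims),
    channel = as.integer((dims - 1L) %/% per_channel + 1L),
    feature = feature_of[within],
    component = component_of[within]
  )
}

#' Tidy a feature selection
#'
#' @param x An `emg_selection`.
#' @param layout The [feature_layout()] used to decode dimension indices.
#' @param ... Unused.
#' @return Tibble with one row per selected dimension: `dim`, `channel`,
#'   `feature`, `component`.
#' @method tidy emg_selection
#' @export
tidy.emg_selection <- function(x, layout = feature_layout(), ...) {
  layout_decode(layout, x$dims)
}

#' @rdname tidy.emg_selection
#' @return For `glance`: a one-row tibble with `method`, `n_dims`,
#'   `fitness`, `n_steps`.
#' @method glance emg_selection
#' @export
glance.emg_selection <- function(x, ...) {
  tibble::tibble(
    method = x$method, n_dims = length(x$dims),
    fitness = x$fitness, n_steps = length(x$trajectory)
  )
}

#' Tidy a fitted SVM model
#'
#' @param x An `emg_svm`.
#' @param ... Unused.
#' @return Tibble of per-class support-vector counts.
#' @method tidy emg_svm
#' @export
tidy.emg_svm <- function(x, ...) {
  tibble::tibble(class = as.character(x$sv_y)) |>
    dplyr::count(.data$class, name = "n_support")
}

#' @rdname tidy.emg_svm
#' @return For `glance`: one row with model-level facts.
#' @method glance emg_svm
#' @export
glance.emg_svm <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$levels),
    n_dims = length(x$center),
    n_support = nrow(x$sv_x),
    cost = x$cost,
    history = paste(x$history, collapse = " -> ")
  )
}

#' Tidy a benchmark summary
#'
#' @param x An `emg_benchmark_summary`.
#' @param ... Unused.
#' @return The per-scheme means tibble (`tidy`) or the paired-ordering
#'   tibble (`glance` returns one row per classifier comparison is too
#'   wide; use `x$orderings` directly for the full table).
#' @method tidy emg_benchmark_summary
#' @export
tidy.emg_benchmark_summary <- function(x, ...) {
  x$schemes
}

#' Accuracy overview of a benchmark run
#'
#' Per-fold accuracies by classifier, facetted by selector and coloured by
#' target day.
#'
#' @param object An `emg_benchmark_result` from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot emg_benchmark_result
#' @export
autoplot.emg_benchmark_result <- function(object, ...) {
  df <- as.data.frame(object)
  df$classifier <- factor(df$classifier, levels = classifier_order)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$classifier, y = .data$accuracy,
    colour = factor(.data$day)
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~selector) +
    ggplot2::labs(
      x = "classifier", y = "test accuracy", colour = "target day",
      title = "Reverse five-fold accuracy by adaptation strategy"
    ) +
    ggplot2::theme_minimal()
}

#' Selection trajectory plot
#'
#' J3 path over SFS steps, or global-best fitness over PSO iterations.
#'
#' @param object An `emg_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot emg_selection
#' @export
autoplot.emg_selection <- function(object, ...) {
  df <- tibble::tibble(
    step = seq_along(object$trajectory) - (object$method == "PSO"),
    value = object$trajectory
  )
  ylab <- if (object$method == "SFS") "J3" else "validation accuracy"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = if (object$method == "SFS") "groups selected" else "iteration",
      y = ylab,
      title = sprintf("%s selection trajectory", object$method)
    ) +
    ggplot2::theme_minimal()
}
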