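#' Adaptation configuration
#'
#' Defaults: calibration consumed in 48-sample batches for incremental
#' adaptation (so a 1,056-vector calibration fifth yields 22 batches), 26
#' TrAdaBoost rounds, linear-SVM cost 1. Source samples whose weight falls
#' below `discard_fraction` times the mean source weight are dropped from a
#' round's training set; calibration samples enter it when their weight is
#' at least `cal_include_factor` times the mean calibration weight.
#'
#' @param batch_size Calibration batch size for incremental adaptation.
#' @param rounds Number of TrAdaBoost rounds `n`.
#' @param cost Linear-SVM cost parameter.
#' @param discard_fraction Source-weight discard threshold (fraction of the
#'   mean source weight).
#' @param cal_include_factor Calibration-weight inclusion threshold
#'   (multiple of the mean calibration weight).
#' @param round_weighting How round models see the boosting weights:
#'   `"subset"` trains on the hard weight-thresholded set; `"replicate"`
#'   additionally replicates samples in proportion to weight.
#' @param cal_selection Pick the round with the most calibration samples by
#'   `"count"` or by total `"weight"`.
#' @param shuffle Shuffle calibration rows (seeded) before batching;
#'   default keeps acquisition order to mimic online arrival.
#' @param seed Seed used when `shuffle = TRUE`.
#' @return An object of class `emg_adaptation_config`.
#' @export
adaptation_config <- function(batch_size = 48L, rounds = 26L, cost = 1,
                              discard_fraction = 0.1, cal_include_factor = 1,
                              round_weighting = c("subset", "replicate"),
                              cal_selection = c("count", "weight"),
                              shuffle = FALSE, seed = 1L) {
  round_weighting <- match.arg(round_weighting)
  cal_selection <- match.arg(cal_selection)
  stopifnot(batch_size >= 1L, rounds >= 2L, cost > 0, discard_fraction >= 0)
  structure(
    list(
      batch_size = as.integer(batch_size), rounds = as.integer(rounds),
      cost = cost, discard_fraction = discard_fraction,
      cal_include_factor = cal_include_factor,
      round_weighting = round_weighting, cal_selection = cal_selection,
      shuffle = shuffle, seed = as.integer(seed)
    ),
    class = "emg_adaptation_config"
  )
}

# Resolve (x, y) from a feature tibble or matrix + labels, applying a
# dimension mask.
resolve_xy <- function(features, labels = NULL, dims = NULL) {
  if (is.data.frame(features)) {
    fm <- feature_matrix(features)
    x <- fm$x
    y <- if (is.null(labels)) fm$y else factor(labels)
  } else {
    x <- as.matrix(features)
    y <- factor(labels)
  }
  if (!is.null(dims)) x <- x[, dims, drop = FALSE]
  list(x = x, y = y)
}

# Fit a linear SVM on raw rows using frozen standardisation. `weights` are
# optional per-sample replication weights (see adaptation_config).
svm_fit_std <- function(x, y, center, scale, cost, replicate_weights = NULL) {
  if (!is.null(replicate_weights)) {
    counts <- pmin(pmax(round(replicate_weights /
                                mean(replicate_weights)), 1L), 8L)
    keep <- rep(seq_along(y), counts)
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
  }
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  fit <- e1071::svm(xs, droplevels(y), kernel = "linear", cost = cost,
                    scale = FALSE)
  list(fit = fit, sv_x = x[fit$index, , drop = FALSE], sv_y = y[fit$index])
}

new_emg_svm <- function(fit, center, scale, levels, dims, cost,
                        sv_x, sv_y, train_x = NULL, train_y = NULL,
                        history = character()) {
  structure(
    list(
      fit = fit, center = center, scale = scale, levels = levels,
      dims = dims, cost = cost, sv_x = sv_x, sv_y = sv_y,
      train_x = train_x, train_y = train_y, history = history
    ),
    class = "emg_svm"
  )
}

#' Train the day-1 base SVM (N-SVM)
#'
#' Fits per-dimension standardisation (mean and standard deviation) on the
#' training vectors, then a one-vs-one linear SVM on the z-scored data. The
#' standardisation is frozen here and reused unchanged by every adaptation
#' strategy on later days. The returned model keeps its raw training rows
#' (needed as the TrAdaBoost source set) and its support-vector rows
#' (needed for incremental adaptation).
#'
#' @param features Day-1 feature tibble (or matrix with `labels`).
#' @param labels Class labels when `features` is a matrix.
#' @param selection An `emg_selection` (or integer dim indices) restricting
#'   the feature columns; `NULL` keeps all.
#' @param config An [adaptation_config()].
#' @return An object of class `emg_svm`.
#' @export
train_base_svm <- function(features, labels = NULL, selection = NULL,
                           config = adaptation_config()) {
  dims <- if (inherits(selection, "emg_selection")) selection$dims
          else selection
  xy <- resolve_xy(features, labels, dims)
  if (nlevels(droplevels(xy$y)) < 2L) {
    abort("Need at least two classes to train an SVM.")
  }
  center <- colMeans(xy$x)
  scale <- apply(xy$x, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  f <- svm_fit_std(xy$x, xy$y, center, scale, config$cost)
  new_emg_svm(
    f$fit, center, scale, levels = levels(droplevels(xy$y)),
    dims = dims, cost = config$cost,
    sv_x = f$sv_x, sv_y = f$sv_y,
    train_x = xy$x, train_y = xy$y,
    history = "base"
  )
}

#' @export
print.emg_svm <- function(x, ...) {
  cat(sprintf(
    "<emg_svm> %d classes, %d dims, %d support vectors [%s]\n",
    length(x$levels), ncol(x$sv_x), nrow(x$sv_x),
    paste(x$history, collapse = " -> ")
  ))
  invisible(x)
}

#' Predict motion labels
#'
#' Applies the model's frozen standardisation (and dimension mask, when the
#' model was trained on a selection) and classifies. With `timing = TRUE`
#' the wall-clock classification time is attached as attribute
#' `response_time_s`.
#'
#' @param object An `emg_svm`.
#' @param newdata Feature tibble or matrix.
#' @param timing Attach the response time.
#' @param ... Unused.
#' @return Factor of predicted labels, one per row of `newdata`.
#' @export
predict.emg_svm <- function(object, newdata, timing = FALSE, ...) {
  xy <- resolve_xy(newdata, labels = NULL, dims = object$dims)
  if (ncol(xy$x) != length(object$center)) {
    abort(sprintf("Model expects %d feature dimensions, got %d.",
                  length(object$center), ncol(xy$x)))
  }
  t0 <- proc.time()[["elapsed"]]
  xs <- sweep(sweep(xy$x, 2L, object$center), 2L, object$scale, "/")
  pred <- factor(as.character(predict(object$fit, xs)),
                 levels = object$levels)
  if (timing) attr(pred, "response_time_s") <- proc.time()[["elapsed"]] - t0
  pred
}

#' Classification accuracy of a model on labelled features
#'
#' @param model An `emg_svm`.
#' @param features Feature tibble with a `label` column (or matrix).
#' @param labels Labels when `features` is a matrix.
#' @return Fraction of correctly classified rows.
#' @export
model_accuracy <- function(model, features, labels = NULL) {
  y <- if (is.data.frame(features)) factor(features$label) else factor(labels)
  mean(as.character(predict(model, features)) == as.character(y))
}
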