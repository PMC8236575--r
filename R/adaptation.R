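#' Batch-incremental SVM adaptation (I-SVM)
#'
#' Consumes the calibration vectors of a target day in order, in batches of
#' `config$batch_size`. Each step retrains the linear SVM on the current
#' support-vector samples together with the next batch, then replaces the
#' support set with the new model's support vectors. Standardisation stays
#' frozen at the day-1 fit. A 1,056-vector calibration fifth at the default
#' batch size of 48 yields 22 adaptation steps.
#'
#' @param model A trained `emg_svm` (the day-1 base model or a TrAdaBoost
#'   product).
#' @param calibration Calibration feature tibble (or matrix with `labels`).
#' @param labels Labels when `calibration` is a matrix.
#' @param config An [adaptation_config()].
#' @return The adapted `emg_svm`.
#' @export
incremental_adapt <- function(model, calibration, labels = NULL,
                              config = adaptation_config()) {
  stopifnot(inherits(model, "emg_svm"))
  xy <- resolve_xy(calibration, labels, model$dims)
  n <- nrow(xy$x)
  if (n == 0L) abort("Calibration set is empty.")
  if (!all(as.character(xy$y) %in% model$levels)) {
    abort("Calibration contains labels outside the model's label set.")
  }
  ord <- seq_len(n)
  if (isTRUE(config$shuffle)) {
    old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(config$seed)
    ord <- sample(n)
  }
  sv_x <- model$sv_x
  sv_y <- model$sv_y
  n_batches <- ceiling(n / config$batch_size)
  fitted <- NULL
  for (b in seq_len(n_batches)) {
    rows <- ord[(((b - 1L) * config$batch_size) + 1L):min(b * config$batch_size, n)]
    bx <- rbind(sv_x, xy$x[rows, , drop = FALSE])
    by <- factor(c(as.character(sv_y), as.character(xy$y[rows])),
                 levels = model$levels)
    fitted <- svm_fit_std(bx, by, model$center, model$scale, config$cost)
    sv_x <- fitted$sv_x
    sv_y <- fitted$sv_y
  }
  new_emg_svm(
    fitted$fit, model$center, model$scale, model$levels, model$dims,
    config$cost, sv_x = sv_x, sv_y = sv_y,
    history = c(model$history, sprintf("incremental(%d batches)", n_batches))
  )
}

# TrAdaBoost source down-weighting factor: beta = 1 / (1 + sqrt(2 ln n_src / n)).
tradaboost_beta <- function(n_source, rounds) {
  1 / (1 + sqrt(2 * log(n_source) / rounds))
}

#' One TrAdaBoost reweighting round
#'
#' Builds the round's training set from the current weights (source samples
#' above the discard threshold, calibration samples at or above the mean
#' calibration weight), trains a linear SVM on it, classifies every sample,
#' and updates the weights: misclassified source samples are multiplied by
#' `beta < 1`, misclassified calibration samples by `(1 - eps)/eps > 1`
#' where `eps` is the weighted calibration error (clipped to
#' `[1e-10, 0.499]`). Weights are renormalised to sum to one.
#'
#' @param x Combined raw feature matrix (source rows first).
#' @param y Factor of labels for `x`.
#' @param origin Character vector, `"source"` or `"calibration"` per row.
#' @param weights Current nonnegative weights (any positive total).
#' @param model_env List with frozen `center`, `scale`, `levels`.
#' @param config An [adaptation_config()].
#' @return List: `model` (`emg_svm` of this round), `weights` (updated,
#'   summing to one), `epsilon`, `active` (logical row mask of the round's
#'   training set), `beta`.
#' @export
tradaboost_round <- function(x, y, origin, weights, model_env,
                             config = adaptation_config()) {
  src <- origin == "source"
  cal <- !src
  if (sum(weights) <= 0) abort("All weights are zero.")
  active <- logical(length(weights))
  active[src] <- weights[src] >= config$discard_fraction * mean(weights[src])
  active[cal] <- weights[cal] >= config$cal_include_factor * mean(weights[cal])
  if (!any(active[cal])) {
    # cannot happen with cal_include_factor <= 1 at uniform weights; guard
    abort("No calibration sample qualified for the round's training set.")
  }
  if (!any(active)) abort("Round training set is empty.")
  rw <- if (config$round_weighting == "replicate") weights[active] else NULL
  f <- svm_fit_std(x[active, , drop = FALSE], y[active],
                   model_env$center, model_env$scale, config$cost,
                   replicate_weights = rw)
  xs <- sweep(sweep(x, 2L, model_env$center), 2L, model_env$scale, "/")
  pred <- factor(as.character(predict(f$fit, xs)), levels = levels(y))
  wrong <- pred != y
  eps <- sum(weights[cal & wrong]) / sum(weights[cal])
  eps <- min(max(eps, 1e-10), 0.499)
  beta <- tradaboost_beta(sum(src), config$rounds)
  w <- weights
  w[src & wrong] <- w[src & wrong] * beta
  w[cal & wrong] <- w[cal & wrong] * (1 - eps) / eps
  w <- w / sum(w)
  model <- new_emg_svm(
    f$fit, model_env$center, model_env$scale, model_env$levels,
    dims = model_env$dims, cost = config$cost,
    sv_x = f$sv_x, sv_y = f$sv_y, history = "tradaboost-round"
  )
  list(model = model, weights = w, epsilon = eps, active = active,
       beta = beta)
}

#' Instance-transfer adaptation by TrAdaBoost (T-SVM)
#'
#' Runs `config$rounds` reweighting rounds over the day-1 training set
#' (source) and the target-day calibration set. Each round trains on the
#' weight-selected combined set and shifts weight away from source samples
#' the round model misclassifies and towards misclassified calibration
#' samples, so rounds progressively discard source data inconsistent with
#' the target day. From the last half of the rounds, the round whose
#' training set contained the most calibration samples is returned (ties go
#' to the latest round).
#'
#' @param model The day-1 base `emg_svm` (its raw training rows are the
#'   source set and its standardisation is reused).
#' @param calibration Calibration feature tibble (or matrix with `labels`).
#' @param labels Labels when `calibration` is a matrix.
#' @param config An [adaptation_config()].
#' @return The selected round's `emg_svm`, with extra fields
#'   `round_history` (tibble: round, epsilon, n_source_active,
#'   n_calibration_active), `selected_round`, and `selected_set`
#'   (list `x`, `y` of that round's training samples, used by
#'   [ti_svm_adapt()]).
#' @export
tradaboost_adapt <- function(model, calibration, labels = NULL,
                             config = adaptation_config()) {
  stopifnot(inherits(model, "emg_svm"))
  if (is.null(model$train_x)) {
    abort("The base model must carry its training rows (train_base_svm).")
  }
  xy <- resolve_xy(calibration, labels, model$dims)
  if (nrow(xy$x) == 0L) abort("Calibration set is empty.")
  x <- rbind(model$train_x, xy$x)
  y <- factor(c(as.character(model$train_y), as.character(xy$y)),
              levels = model$levels)
  origin <- rep(c("source", "calibration"),
                c(nrow(model$train_x), nrow(xy$x)))
  weights <- rep(1 / length(y), length(y))
  model_env <- list(center = model$center, scale = model$scale,
                    levels = model$levels, dims = model$dims)
  rounds <- vector("list", config$rounds)
  hist <- tibble::tibble(
    round = seq_len(config$rounds), epsilon = NA_real_,
    n_source_active = NA_integer_, n_calibration_active = NA_integer_,
    calibration_weight = NA_real_
  )
  for (t in seq_len(config$rounds)) {
    r <- tradaboost_round(x, y, origin, weights, model_env, config)
    weights <- r$weights
    rounds[[t]] <- r
    hist$epsilon[t] <- r$epsilon
    hist$n_source_active[t] <- sum(r$active & origin == "source")
    hist$n_calibration_active[t] <- sum(r$active & origin == "calibration")
    hist$calibration_weight[t] <- sum(weights[origin == "calibration"])
  }
  eligible <- (ceiling(config$rounds / 2) + 1L):config$rounds
  crit <- if (config$cal_selection == "count") {
    hist$n_calibration_active[eligible]
  } else {
    vapply(eligible, function(t) {
      sum(rounds[[t]]$weights[rounds[[t]]$active & origin == "calibration"])
    }, numeric(1))
  }
  best <- eligible[max(which(crit == max(crit)))]
  sel <- rounds[[best]]
  out <- sel$model
  out$history <- c(model$history,
                   sprintf("tradaboost(round %d of %d)", best, config$rounds))
  out$round_history <- hist
  out$selected_round <- best
  out$selected_set <- list(x = x[sel$active, , drop = FALSE],
                           y = y[sel$active])
  out
}

#' TrAdaBoost set construction followed by incremental adaptation (TI-SVM)
#'
#' Three stages: (1) run [tradaboost_adapt()] to obtain the selected
#' round's combined training set; (2) train a fresh linear SVM on that set
#' (frozen day-1 standardisation); (3) incrementally adapt it with the full
#' calibration set in the usual batches.
#'
#' @inheritParams tradaboost_adapt
#' @return The adapted `emg_svm`.
#' @export
ti_svm_adapt <- function(model, calibration, labels = NULL,
                         config = adaptation_config()) {
  tb <- tradaboost_adapt(model, calibration, labels, config)
  f <- svm_fit_std(tb$selected_set$x, tb$selected_set$y,
                   model$center, model$scale, config$cost)
  fresh <- new_emg_svm(
    f$fit, model$center, model$scale, model$levels, model$dims, config$cost,
    sv_x = f$sv_x, sv_y = f$sv_y,
    history = c(model$history,
                sprintf("tradaboost(round %d of %d)", tb$selected_round,
                        config$rounds))
  )
  incremental_adapt(fresh, calibration, labels, config)
}
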