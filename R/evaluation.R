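#' Reverse five-fold plan for one target day
#'
#' Splits a day's windows into five stratified folds. In the reverse
#' protocol each fold's held-IN fifth is the calibration set used to adapt
#' the model and the held-OUT four fifths are the test set — the inversion
#' of conventional cross-validation, reflecting that labelled recalibration
#' data is the scarce resource in repeated uses. Across the five folds the
#' calibration fifths partition the day exactly.
#'
#' @param features Feature tibble of one target day (needs a `label`
#'   column).
#' @param seed Seed for the stratified shuffle.
#' @param n_folds Number of folds.
#' @return A tibble of class `emg_fold_plan` with columns `fold`,
#'   `calibration`, `test` (list-columns of row indices).
#' @export
make_fold_plan <- function(features, seed = 1L, n_folds = 5L) {
  y <- factor(features$label)
  counts <- table(y)
  if (any(counts < n_folds)) {
    abort(sprintf(
      "Every class needs at least %d windows; smallest has %d.",
      n_folds, min(counts)
    ))
  }
  assignment <- integer(length(y))
  with_seed(seed, {
    for (l in levels(y)) {
      rows <- sample(which(y == l))
      assignment[rows] <- rep_len(seq_len(n_folds), length(rows))
    }
  })
  out <- tibble::tibble(
    fold = seq_len(n_folds),
    calibration = lapply(seq_len(n_folds), function(k) which(assignment == k)),
    test = lapply(seq_len(n_folds), function(k) which(assignment != k))
  )
  class(out) <- c("emg_fold_plan", class(out))
  out
}

adapt_model <- function(classifier, base, calibration, config) {
  switch(classifier,
    nsvm = base,
    isvm = incremental_adapt(base, calibration, config = config),
    tsvm = tradaboost_adapt(base, calibration, config = config),
    tisvm = ti_svm_adapt(base, calibration, config = config),
    abort(sprintf("Unknown classifier '%s'.", classifier))
  )
}

#' Evaluate one selector/classifier combination on target days
#'
#' Trains the day-1 base model once on the selected dimensions, then for
#' every fold of every target day adapts it per the classifier contract on
#' the fold's calibration fifth and scores it on the fold's test set.
#' Training time covers the base fit plus adaptation (base fit only for
#' N-SVM, which never adapts); response time is the wall-clock time to
#' classify the test set.
#'
#' @param day1_features Day-1 feature tibble.
#' @param target_features Named list (or single tibble) of target-day
#'   feature tibbles.
#' @param fold_plans List of [make_fold_plan()] results aligned with
#'   `target_features`.
#' @param classifier One of `"nsvm"`, `"isvm"`, `"tsvm"`, `"tisvm"`.
#' @param selection An `emg_selection` (or `NULL` for all dimensions).
#' @param config An [adaptation_config()].
#' @param base Optionally, the already-trained day-1 base model (so several
#'   classifiers share one base fit); trained here when `NULL`.
#' @param base_time Wall-clock seconds spent training `base` (measured here
#'   when the base is trained here).
#' @return Tibble with one row per (day, fold): `classifier`, `day`,
#'   `fold`, `accuracy`, `train_time_s`, `response_time_s`.
#' @export
evaluate_combination <- function(day1_features, target_features, fold_plans,
                                 classifier = c("nsvm", "isvm", "tsvm", "tisvm"),
                                 selection = NULL,
                                 config = adaptation_config(),
                                 base = NULL, base_time = NULL) {
  classifier <- match.arg(classifier)
  if (is.data.frame(target_features)) target_features <- list(target_features)
  if (inherits(fold_plans, "emg_fold_plan")) fold_plans <- list(fold_plans)
  if (is.null(base)) {
    t0 <- proc.time()[["elapsed"]]
    base <- train_base_svm(day1_features, selection = selection,
                           config = config)
    base_time <- proc.time()[["elapsed"]] - t0
  }
  rows <- list()
  for (k in seq_along(target_features)) {
    feats <- target_features[[k]]
    plan <- fold_plans[[k]]
    day <- feats$day[1L]
    for (f in seq_len(nrow(plan))) {
      cal <- feats[plan$calibration[[f]], , drop = FALSE]
      tst <- feats[plan$test[[f]], , drop = FALSE]
      t1 <- proc.time()[["elapsed"]]
      model <- adapt_model(classifier, base, cal, config)
      adapt_time <- proc.time()[["elapsed"]] - t1
      pred <- predict(model, tst, timing = TRUE)
      acc <- mean(as.character(pred) == as.character(tst$label))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        classifier = classifier, day = day, fold = f, accuracy = acc,
        train_time_s = base_time +
          if (classifier == "nsvm") 0 else adapt_time,
        response_time_s = attr(pred, "response_time_s")
      )
    }
  }
  dplyr::bind_rows(rows)
}

run_selection <- function(selector, day1_features, layout, pso_cfg) {
  switch(selector,
    nfs = nfs_select(day1_features),
    sfs = sfs_select(day1_features, layout = layout),
    pso = pso_select(day1_features, config = pso_cfg),
    abort(sprintf("Unknown selector '%s'.", selector))
  )
}

#' Run the multi-day benchmark end to end
#'
#' For each subject: generate the synthetic recordings (day 1 plus the
#' target days), segment and extract features, run each feature selector on
#' the day-1 vectors only, and evaluate each classifier under the reverse
#' five-fold protocol on each target day. Feature dimensions chosen on day
#' 1 are applied unchanged to later days.
#'
#' @param config An [benchmark_config()].
#' @param selectors Subset of `c("nfs", "sfs", "pso")`.
#' @param classifiers Subset of `c("nsvm", "isvm", "tsvm", "tisvm")`.
#' @param target_days Days evaluated against day 1.
#' @param spec Sliding-window specification.
#' @param adapt_cfg An [adaptation_config()].
#' @param pso_cfg An [pso_config()] (used when `"pso"` is requested).
#' @param n_folds Folds per target day.
#' @param windows_per_trial Keep only this many evenly spaced windows per
#'   trial (`NULL` keeps all). A problem-size control for desk-scale runs;
#'   the protocol (day-1 selection, reverse folds, batch sizes, rounds) is
#'   unchanged.
#' @param seed Seed for fold plans (and PSO unless `pso_cfg` overrides).
#' @return Tibble of class `emg_benchmark_result`: one row per
#'   (subject, selector, classifier, day, fold) with accuracy and timings.
#' @export
run_benchmark <- function(config = benchmark_config(),
                          selectors = c("nfs"),
                          classifiers = c("nsvm", "isvm", "tsvm", "tisvm"),
                          target_days = 2:config$n_days,
                          spec = window_spec(),
                          adapt_cfg = adaptation_config(),
                          pso_cfg = NULL,
                          n_folds = 5L,
                          windows_per_trial = NULL,
                          seed = 1L) {
  layout <- feature_layout(config$channels)
  rows <- list()
  for (s in seq_len(config$n_subjects)) {
    sessions <- generate_benchmark(config, subjects = s,
                                   days = c(1L, target_days))
    windows <- segment_session(sessions, spec,
                               keep_central_s = config$keep_central_s)
    if (!is.null(windows_per_trial)) {
      keep <- unique(round(seq(1L, max(windows$window),
                               length.out = windows_per_trial)))
      windows <- windows[windows$window %in% keep, , drop = FALSE]
    }
    features <- extract_features(windows, config$sampling_rate)
    day1 <- features[features$day == 1L, , drop = FALSE]
    targets <- lapply(target_days, function(d) {
      features[features$day == d, , drop = FALSE]
    })
    plans <- lapply(seq_along(target_days), function(k) {
      make_fold_plan(targets[[k]],
                     seed = derive_seed(seed, s, target_days[k], 303),
                     n_folds = n_folds)
    })
    for (sel in selectors) {
      pcfg <- pso_cfg %||% pso_config(seed = derive_seed(seed, s, 404))
      selection <- run_selection(sel, day1, layout, pcfg)
      t0 <- proc.time()[["elapsed"]]
      base <- train_base_svm(day1, selection = selection, config = adapt_cfg)
      base_time <- proc.time()[["elapsed"]] - t0
      for (cls in classifiers) {
        res <- evaluate_combination(day1, targets, plans, classifier = cls,
                                    selection = selection, config = adapt_cfg,
                                    base = base, base_time = base_time)
        res$subject <- paste0("S", s)
        res$selector <- toupper(sel)
        res$n_dims <- length(selection$dims)
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::select(out, "subject", "selector", "classifier", "day",
                       "fold", "accuracy", "train_time_s", "response_time_s",
                       "n_dims")
  class(out) <- c("emg_benchmark_result", class(out))
  out
}

classifier_order <- c("nsvm", "isvm", "tsvm", "tisvm")

#' Summarise a benchmark run
#'
#' Per-scheme (selector by classifier) mean and standard deviation of
#' accuracy and timings, plus paired per-subject comparisons between
#' classifiers within each selector: mean accuracy difference, how many
#' subjects favour the first method, and a sign-test and paired
#' Wilcoxon-style p-value for the direction.
#'
#' @param results An `emg_benchmark_result` from [run_benchmark()].
#' @return List of class `emg_benchmark_summary` with `schemes` and
#'   `orderings` tibbles.
#' @export
summarize_benchmark <- function(results) {
  missing <- dplyr::anti_join(
    tidyr::expand_grid(
      subject = unique(results$subject), selector = unique(results$selector),
      classifier = unique(results$classifier), day = unique(results$day)
    ),
    results,
    by = c("subject", "selector", "classifier", "day")
  )
  if (nrow(missing) > 0L) {
    abort(paste(
      "Benchmark results are incomplete; missing cells:",
      paste(utils::capture.output(print(missing)), collapse = "\n")
    ))
  }
  schemes <- results |>
    dplyr::group_by(.data$selector, .data$classifier) |>
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy),
      sd_accuracy = sd(.data$accuracy),
      mean_train_time_s = mean(.data$train_time_s),
      mean_response_time_s = mean(.data$response_time_s),
      .groups = "drop"
    )
  per_subject <- results |>
    dplyr::group_by(.data$subject, .data$selector, .data$classifier) |>
    dplyr::summarise(accuracy = mean(.data$accuracy), .groups = "drop")
  pairs <- list(
    c("tisvm", "isvm"), c("tisvm", "tsvm"), c("tisvm", "nsvm"),
    c("isvm", "tsvm"), c("isvm", "nsvm"), c("tsvm", "nsvm")
  )
  orderings <- list()
  for (sel in unique(per_subject$selector)) {
    for (p in pairs) {
      if (!all(p %in% unique(results$classifier))) next
      a <- per_subject[per_subject$selector == sel &
                         per_subject$classifier == p[1L], ]
      b <- per_subject[per_subject$selector == sel &
                         per_subject$classifier == p[2L], ]
      d <- a$accuracy[match(b$subject, a$subject)] - b$accuracy
      n_pos <- sum(d > 0)
      n_nonzero <- sum(d != 0)
      sign_p <- if (n_nonzero > 0) {
        stats::binom.test(n_pos, n_nonzero, alternative = "greater")$p.value
      } else 1
      wil_p <- if (n_nonzero > 0 && length(d) > 1L) {
        suppressWarnings(
          stats::wilcox.test(d, alternative = "greater", exact = FALSE)$p.value
        )
      } else NA_real_
      orderings[[length(orderings) + 1L]] <- tibble::tibble(
        selector = sel, better = p[1L], worse = p[2L],
        mean_difference = mean(d), n_subjects = length(d),
        n_subjects_better = n_pos, sign_test_p = sign_p,
        wilcoxon_p = wil_p
      )
    }
  }
  structure(
    list(schemes = schemes, orderings = dplyr::bind_rows(orderings)),
    class = "emg_benchmark_summary"
  )
}

#' @export
print.emg_benchmark_summary <- function(x, ...) {
  cat("Scheme means (accuracy fraction, times in seconds):\n")
  print(x$schemes, n = Inf)
  cat("\nPaired per-subject classifier comparisons:\n")
  print(x$orderings, n = Inf)
  invisible(x)
}
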