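sep_centers <- function(k = 3, d = 4, gap = 12) {
  m <- matrix(0, k, d)
  for (i in seq_len(k)) m[i, ((i - 1) %% d) + 1] <- gap
  m
}

test_that("base SVM fits, standardises once, and rejects degenerate input", {
  f <- make_gaussian_features(sep_centers(), n_per_class = 20, sd = 0.5,
                              seed = 31)
  m <- train_base_svm(f)
  expect_s3_class(m, "emg_svm")
  expect_equal(model_accuracy(m, f), 1.0)
  expect_identical(sort(m$levels), c("C1", "C2", "C3"))

  # column rescaling is absorbed by standardisation: same predictions
  f2 <- f
  f2$dim_0001 <- f2$dim_0001 * 1000
  m2 <- train_base_svm(f2)
  expect_identical(as.character(predict(m2, f2)),
                   as.character(predict(m, f)))

  f1 <- f[f$label == "C1", ]
  expect_error(train_base_svm(f1), "two classes")
})

test_that("predict enforces dimensions and is stateless over row order", {
  f <- make_gaussian_features(sep_centers(), n_per_class = 15, sd = 0.5,
                              seed = 32)
  m <- train_base_svm(f)
  p <- predict(m, f)
  expect_length(p, nrow(f))
  perm <- sample(nrow(f))
  expect_identical(as.character(predict(m, f[perm, ])),
                   as.character(p)[perm])
  expect_error(predict(m, as.matrix(f[, 1:2])), "dimensions")
  t <- predict(m, f, timing = TRUE)
  expect_gte(attr(t, "response_time_s"), 0)
})

test_that("incremental adaptation batches the calibration stream in order", {
  f <- make_gaussian_features(sep_centers(), n_per_class = 40, sd = 0.5,
                              seed = 33)
  m <- train_base_svm(f)
  cal <- make_gaussian_features(sep_centers(), n_per_class = 34, sd = 0.5,
                                seed = 34)
  # 102 calibration rows at batch 48 -> 3 adaptation steps
  a <- incremental_adapt(m, cal)
  expect_match(tail(a$history, 1), "3 batches")

  # same-distribution separable data: accuracy stays perfect
  tst <- make_gaussian_features(sep_centers(), n_per_class = 20, sd = 0.5,
                                seed = 35)
  expect_equal(model_accuracy(a, tst), 1.0)

  # labels outside the model's set are rejected
  bad <- cal
  bad$label[1] <- "C9"
  expect_error(incremental_adapt(m, bad), "outside")
  expect_error(incremental_adapt(m, cal[0, ]), "empty")
})

test_that("incremental adaptation helps under distribution shift", {
  wins <- 0
  n_rep <- 10
  for (r in seq_len(n_rep)) {
    days <- make_shifted_days(n_classes = 4, d = 6, n_per_class = 30,
                              shift = 2.5, seed = 40 + r)
    m <- train_base_svm(days$day1)
    cal_rows <- unlist(lapply(split(seq_len(nrow(days$day2)),
                                    days$day2$label), head, 6))
    cal <- days$day2[cal_rows, ]
    tst <- days$day2[-cal_rows, ]
    a <- incremental_adapt(m, cal, config = adaptation_config(batch_size = 8))
    if (model_accuracy(a, tst) >= model_accuracy(m, tst)) wins <- wins + 1
  }
  expect_gte(wins / n_rep, 0.8)
})

test_that("incremental result stays close to a from-scratch refit", {
  # sanity bound: on a small same-distribution problem the order-dependent
  # incremental path lands within 2% of retraining on SVs + calibration
  f <- make_gaussian_features(sep_centers(4, 5, gap = 6), n_per_class = 25,
                              sd = 1.2, seed = 50)
  m <- train_base_svm(f)
  cal <- make_gaussian_features(sep_centers(4, 5, gap = 6), n_per_class = 12,
                                sd = 1.2, seed = 51)
  tst <- make_gaussian_features(sep_centers(4, 5, gap = 6), n_per_class = 25,
                                sd = 1.2, seed = 52)
  inc <- incremental_adapt(m, cal, config = adaptation_config(batch_size = 16))
  scratch_x <- rbind(m$sv_x, feature_matrix(cal)$x)
  scratch_y <- c(as.character(m$sv_y), as.character(feature_matrix(cal)$y))
  scratch <- train_base_svm(scratch_x, scratch_y)
  expect_lt(abs(model_accuracy(inc, tst) - model_accuracy(scratch, tst)),
            0.02 + 1e-9)
})

test_that("TrAdaBoost beta matches its closed form", {
  expect_equal(emgadapt:::tradaboost_beta(4224, 26),
               1 / (1 + sqrt(2 * log(4224) / 26)))
})

overlap_setup <- function(seed = 60, shift = 3) {
  # overlapping classes so round models do misclassify
  days <- make_shifted_days(n_classes = 3, d = 3, n_per_class = 40,
                            sd = 2.5, shift = shift, seed = seed)
  base <- train_base_svm(days$day1)
  cal_rows <- unlist(lapply(split(seq_len(nrow(days$day2)),
                                  days$day2$label), head, 8))
  list(base = base, cal = days$day2[cal_rows, ],
       tst = days$day2[-cal_rows, ], day1 = days$day1)
}

test_that("a TrAdaBoost round moves weight in the documented directions", {
  su <- overlap_setup()
  xy_cal <- feature_matrix(su$cal)
  x <- rbind(su$base$train_x, xy_cal$x)
  y <- factor(c(as.character(su$base$train_y), as.character(xy_cal$y)),
              levels = su$base$levels)
  origin <- rep(c("source", "calibration"),
                c(nrow(su$base$train_x), nrow(xy_cal$x)))
  w0 <- rep(1 / length(y), length(y))
  env <- list(center = su$base$center, scale = su$base$scale,
              levels = su$base$levels, dims = NULL)
  r <- tradaboost_round(x, y, origin, w0, env, adaptation_config())
  expect_equal(sum(r$weights), 1, tolerance = 1e-12)
  pred <- predict(r$model, x)
  wrong <- as.character(pred) != as.character(y)
  expect_gt(sum(wrong & origin == "source"), 0)
  # before renormalisation the update is multiplicative; after it, the
  # *relative* weight of wrong source samples falls and wrong calibration
  # samples rises compared to their correctly classified peers
  w_rel <- r$weights / w0
  expect_true(all(w_rel[wrong & origin == "source"] <
                    w_rel[!wrong & origin == "source"][1] - 1e-12))
  if (any(wrong & origin == "calibration")) {
    expect_true(all(w_rel[wrong & origin == "calibration"] >
                      w_rel[!wrong & origin == "calibration"][1] + 1e-12))
  }
  expect_gt(r$epsilon, 0)
  expect_lt(r$epsilon, 0.5)
})

test_that("a round with no misclassification leaves weights untouched", {
  f <- make_gaussian_features(sep_centers(), n_per_class = 15, sd = 0.3,
                              seed = 61)
  base <- train_base_svm(f)
  cal <- make_gaussian_features(sep_centers(), n_per_class = 5, sd = 0.3,
                                seed = 62)
  xy <- feature_matrix(cal)
  x <- rbind(base$train_x, xy$x)
  y <- factor(c(as.character(base$train_y), as.character(xy$y)),
              levels = base$levels)
  origin <- rep(c("source", "calibration"), c(nrow(base$train_x), nrow(xy$x)))
  w0 <- rep(1 / length(y), length(y))
  env <- list(center = base$center, scale = base$scale,
              levels = base$levels, dims = NULL)
  r <- tradaboost_round(x, y, origin, w0, env, adaptation_config())
  expect_equal(r$weights, w0, tolerance = 1e-12)
})

test_that("TrAdaBoost adaptation runs n rounds and selects from the last half", {
  su <- overlap_setup()
  cfg <- adaptation_config(rounds = 26)
  tb <- tradaboost_adapt(su$base, su$cal, config = cfg)
  expect_equal(nrow(tb$round_history), 26)
  expect_gte(tb$selected_round, 14)
  expect_lte(tb$selected_round, 26)
  expect_true(all(is.finite(tb$round_history$epsilon)))
})

test_that("source discards concentrate in a class that moved", {
  days <- make_shifted_days(n_classes = 3, d = 3, n_per_class = 40,
                            sd = 1.5, shift = 0, seed = 71)
  moved <- days$day2
  moved[moved$label == "C1", 1:3] <- moved[moved$label == "C1", 1:3] + 7
  base <- train_base_svm(days$day1)
  cal_rows <- unlist(lapply(split(seq_len(nrow(moved)), moved$label),
                            head, 10))
  cfg <- adaptation_config(rounds = 10)
  tb <- tradaboost_adapt(base, moved[cal_rows, ], config = cfg)
  # recompute survival from the selected round's training set composition
  n_src <- nrow(base$train_x)
  sel_x <- tb$selected_set$x
  # source rows of the selected set are the rows drawn from train_x; count
  # per class by matching labels in order (source rows come first)
  n_src_kept <- sum(tb$round_history$n_source_active[tb$selected_round])
  kept_labels <- as.character(tb$selected_set$y[seq_len(n_src_kept)])
  orig <- table(as.character(base$train_y))
  kept <- table(factor(kept_labels, levels = names(orig)))
  survival <- as.numeric(kept) / as.numeric(orig)
  names(survival) <- names(orig)
  expect_lte(survival[["C1"]], min(survival[["C2"]], survival[["C3"]]))
})

test_that("TI-SVM composes TrAdaBoost set construction with incremental", {
  f <- make_gaussian_features(sep_centers(), n_per_class = 30, sd = 0.4,
                              seed = 80)
  base <- train_base_svm(f)
  cal <- make_gaussian_features(sep_centers(), n_per_class = 10, sd = 0.4,
                                seed = 81)
  tst <- make_gaussian_features(sep_centers(), n_per_class = 20, sd = 0.4,
                                seed = 82)
  cfg <- adaptation_config(rounds = 6, batch_size = 16)
  ti <- ti_svm_adapt(base, cal, config = cfg)
  # no shift, separable: perfect accuracy retained
  expect_equal(model_accuracy(ti, tst), 1.0)
  # deterministic: identical inputs give identical predictions
  ti2 <- ti_svm_adapt(base, cal, config = cfg)
  expect_identical(as.character(predict(ti, tst)),
                   as.character(predict(ti2, tst)))
  expect_match(paste(ti$history, collapse = " "), "tradaboost")
  expect_match(paste(ti$history, collapse = " "), "incremental")
})
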