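# Small data builders shared across test files.

make_trial <- function(channels = 7, n = 10500, rate = 1500, motion = "SF",
                       trial_index = 1, day = 1, subject = "S1", seed = 1) {
  set.seed(seed)
  emg_trial(matrix(rnorm(channels * n, sd = 30), channels, n), rate, motion,
            trial_index = trial_index, day = day, subject = subject)
}

# Gaussian class clusters as a feature tibble: `centers` is a classes x dims
# matrix of class means.
make_gaussian_features <- function(centers, n_per_class = 20, sd = 1,
                                   seed = 1, day = 1) {
  set.seed(seed)
  k <- nrow(centers)
  d <- ncol(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    sweep(matrix(rnorm(n_per_class * d, sd = sd), n_per_class, d),
          2, centers[i, ], "+")
  }))
  colnames(x) <- sprintf("dim_%04d", seq_len(d))
  dplyr::bind_cols(
    tibble::as_tibble(x),
    tibble::tibble(
      label = rep(paste0("C", seq_len(k)), each = n_per_class),
      subject = "S1", day = day,
      trial = rep(seq_len(n_per_class), times = k),
      window = seq_len(k * n_per_class)
    )
  )
}

# Two-day pair of feature tibbles with a controllable mean shift applied to
# day 2 (same cluster geometry otherwise).
make_shifted_days <- function(n_classes = 4, d = 6, n_per_class = 30,
                              sd = 1, shift = 1.5, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(n_classes * d, sd = 4), n_classes, d)
  day1 <- make_gaussian_features(centers, n_per_class, sd, seed = seed + 1)
  drift <- matrix(rnorm(n_classes * d, sd = shift), n_classes, d)
  day2 <- make_gaussian_features(centers + drift, n_per_class, sd,
                                 seed = seed + 2, day = 2)
  list(day1 = day1, day2 = day2)
}
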