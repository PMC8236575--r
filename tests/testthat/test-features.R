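test_that("amplitude features match hand arithmetic and the loop oracle", {
  f <- amplitude_features(c(1, -1, 1, -1))
  expect_equal(f[["MAV"]], 1)
  expect_equal(f[["RMS"]], 1)
  expect_equal(f[["WL"]], 6)
  expect_equal(f[["VAR"]], 4 / 3)

  expect_equal(unname(amplitude_features(rep(0, 10))), rep(0, 4))

  set.seed(3)
  x <- rnorm(375, sd = 40)
  expect_equal(amplitude_features(x), oracle_amplitude(x), tolerance = 1e-12)

  expect_error(amplitude_features(5), "at least 2")
})

test_that("threshold features count the defining events", {
  expect_equal(threshold_features(c(30, -30, 30))[["ZC"]], 2)
  expect_equal(threshold_features(c(0, 20, 0))[["SSC"]], 1)
  # monotone ramp: no slope sign change; non-negative vector: no crossing
  ramp <- seq(0, 100, length.out = 50)
  expect_equal(threshold_features(ramp)[["SSC"]], 0)
  expect_equal(threshold_features(abs(rnorm(50, sd = 30)))[["ZC"]], 0)

  set.seed(4)
  x <- rnorm(375, sd = 40)
  expect_equal(threshold_features(x), oracle_threshold(x, 10, 25))
})

test_that("amplitude/threshold features obey the scaling laws", {
  set.seed(5)
  x <- rnorm(375, sd = 30)
  a <- 3.7
  f1 <- amplitude_features(x)
  f2 <- amplitude_features(a * x)
  expect_equal(f2[["MAV"]], a * f1[["MAV"]])
  expect_equal(f2[["RMS"]], a * f1[["RMS"]])
  expect_equal(f2[["WL"]], a * f1[["WL"]])
  expect_equal(f2[["VAR"]], a^2 * f1[["VAR"]])
  # counts invariant when thresholds scale with the signal (SSC by a^2)
  p1 <- feature_params()
  p2 <- feature_params(ssc_threshold = 10 * a^2, zc_threshold = 25 * a)
  expect_equal(threshold_features(x, p1), threshold_features(a * x, p2))
})

test_that("AR coefficients recover known processes and match ar.burg", {
  set.seed(6)
  # white noise: no autocorrelation structure
  a <- ar_coefficients(rnorm(4096), 5)
  expect_length(a, 5)
  expect_true(all(abs(a) < 0.1))

  # AR(1) parameter recovery
  x <- as.numeric(arima.sim(list(ar = 0.9), n = 8192))
  expect_equal(ar_coefficients(x, 1), 0.9, tolerance = 0.05,
               ignore_attr = TRUE)

  # both orders, cross-checked against the reference Burg implementation
  y <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), n = 2000))
  for (p in c(5L, 6L)) {
    mine <- ar_coefficients(y, p)
    expect_length(mine, p)
    ref <- stats::ar.burg(y, aic = FALSE, order.max = p, demean = FALSE)$ar
    expect_equal(mine, ref, tolerance = 1e-10)
  }

  expect_warning(z <- ar_coefficients(rep(2, 100), 5), "Constant")
  expect_equal(z, rep(0, 5))
})

test_that("cepstral recursion matches hand values and the spectral route", {
  expect_equal(cepstral_coefficients(0.5, 1), -0.5)
  expect_equal(cepstral_coefficients(rep(0, 6), 5), rep(0, 5))
  # c2 = -a2 - (1 - 1/2) a1 c1 with a = (0.5, 0.25)
  expect_equal(cepstral_coefficients(c(0.5, 0.25), 2), c(-0.5, -0.125))

  # numerical cross-check: the recursion reproduces the complex cepstrum of
  # 1 / (1 + sum_k a_k z^-k), computed via the log spectrum on a dense grid
  a <- c(0.4, -0.15, 0.08)
  nfft <- 4096
  w <- 2 * pi * (0:(nfft - 1)) / nfft
  A <- 1 + sapply(w, function(om) sum(a * exp(-1i * om * seq_along(a))))
  ceps <- Re(fft(log(1 / A), inverse = TRUE)) / nfft
  expect_equal(cepstral_coefficients(a, 3), ceps[2:4], tolerance = 1e-6)

  expect_error(cepstral_coefficients(c(0.5, 0.2), 3), "exceed")
})

test_that("spectral features locate a pure tone and match the cumsum oracle", {
  rate <- 1500
  n <- 375
  x <- sin(2 * pi * 100 * (1:n) / rate)
  sp <- spectral_features(x, rate)
  expect_lt(abs(sp[["MNF"]] - 100), 4)
  expect_lt(abs(sp[["MDF"]] - 100), 4)

  # two equal-power, bin-aligned tones: MNF is their midpoint, MDF between
  f1 <- 80
  f2 <- 240 # both multiples of rate/n = 4 Hz
  y <- sin(2 * pi * f1 * (1:n) / rate) + sin(2 * pi * f2 * (1:n) / rate)
  sp2 <- spectral_features(y, rate)
  expect_equal(sp2[["MNF"]], (f1 + f2) / 2, tolerance = 1)
  expect_gte(sp2[["MDF"]], f1)
  expect_lte(sp2[["MDF"]], f2)

  set.seed(7)
  for (i in 1:10) {
    z <- rnorm(375, sd = 20)
    expect_equal(spectral_features(z, rate)[["MDF"]], oracle_mdf(z, rate))
  }

  expect_error(spectral_features(rep(0, 375), rate), "Zero-power")
})

test_that("wavelet features equal direct formulas on an independent DWT", {
  z <- wavelet_features(rep(0, 375))
  expect_length(z, 18)
  expect_true(all(z == 0))
  expect_equal(sum(startsWith(names(z), "WTWL")), 6)
  expect_equal(sum(startsWith(names(z), "WTVAR")), 6)
  expect_equal(sum(startsWith(names(z), "WTMAV")), 6)

  set.seed(8)
  x <- rnorm(375, sd = 25)
  mine <- wavelet_features(x)
  ref <- oracle_dwt(x, 5)
  for (band in c("cA5", paste0("cD", 1:5))) {
    b <- ref[[band]]
    expect_equal(mine[[paste0("WTWL_", band)]], sum(abs(diff(b))),
                 tolerance = 1e-10)
    expect_equal(mine[[paste0("WTVAR_", band)]],
                 sum(b^2) / (length(b) - 1), tolerance = 1e-10)
    expect_equal(mine[[paste0("WTMAV_", band)]], mean(abs(b)),
                 tolerance = 1e-10)
  }

  expect_error(dwt_db2(rnorm(50), 5), "minimum 96")
})

test_that("the full feature vector follows the channel-major layout", {
  set.seed(9)
  w7 <- matrix(rnorm(7 * 375, sd = 30), 7, 375)
  v <- extract_feature_vector(w7, 1500)
  expect_length(v, 294)
  expect_true(all(is.finite(v)))

  v1 <- extract_feature_vector(w7[1, , drop = FALSE], 1500)
  expect_length(v1, 42)

  # identical signal on all channels: the 42-dim block repeats 7 times
  same <- matrix(rep(w7[1, ], 7), 7, byrow = TRUE)
  vs <- extract_feature_vector(same, 1500)
  for (c in 2:7) {
    expect_equal(unname(vs[((c - 1) * 42 + 1):(c * 42)]), unname(vs[1:42]))
  }

  # determinism
  expect_identical(v, extract_feature_vector(w7, 1500))
})

test_that("layout indexing retrieves the standalone extractor values", {
  layout <- feature_layout(7)
  expect_equal(layout_total(layout), 294)
  groups <- feature_groups(layout)
  expect_equal(sort(unname(unlist(groups))), 1:294)
  expect_equal(lengths(groups)[["MAV"]], 7)
  expect_equal(lengths(groups)[["AR6"]], 42)

  set.seed(10)
  w <- matrix(rnorm(7 * 375, sd = 30), 7, 375)
  v <- extract_feature_vector(w, 1500)
  for (ch in c(1, 4, 7)) {
    expect_equal(v[[layout_index(layout, "MAV", ch)]],
                 amplitude_features(w[ch, ])[["MAV"]])
    expect_equal(v[[layout_index(layout, "ZC", ch)]],
                 threshold_features(w[ch, ])[["ZC"]])
    expect_equal(v[[layout_index(layout, "AR6", ch, 3)]],
                 ar_coefficients(w[ch, ], 6)[3])
    expect_equal(v[[layout_index(layout, "CC", ch, 2)]],
                 cepstral_coefficients(ar_coefficients(w[ch, ], 6), 5)[2])
    expect_equal(v[[layout_index(layout, "MDF", ch)]],
                 spectral_features(w[ch, ], 1500)[["MDF"]])
    expect_equal(v[[layout_index(layout, "WTMAV", ch, 1)]],
                 wavelet_features(w[ch, ])[["WTMAV_cA5"]])
  }
})

test_that("table extraction agrees with the single-window path", {
  tr <- make_trial(channels = 7, n = 1500, seed = 11)
  w <- segment_trial(tr, window_spec(250, 250))
  f <- extract_features(w, 1500)
  expect_equal(sum(grepl("^dim_", names(f))), 294)
  expect_equal(nrow(f), 4)
  expect_identical(f$label, rep("SF", 4))
  for (k in c(1, 4)) {
    expect_equal(
      unname(as.matrix(f[k, 1:294])[1, ]),
      unname(extract_feature_vector(w$samples[[k]], 1500)),
      tolerance = 1e-12
    )
  }
})
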