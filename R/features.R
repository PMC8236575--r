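#' Feature-extraction parameters
#'
#' Defaults follow common myoelectric-control practice: slope-sign-change
#' threshold 10 and zero-crossing threshold 25 (in the signal's native
#' amplitude units), autoregressive models of order 5 and 6, five cepstral
#' coefficients derived from the order-6 fit, and a five-level db2 wavelet
#' decomposition.
#'
#' @param ssc_threshold Threshold on the slope product for SSC counting
#'   (amplitude-squared units).
#' @param zc_threshold Minimum jump size for a zero crossing to count
#'   (amplitude units).
#' @param ar_orders Orders of the two autoregressive fits.
#' @param cc_order Number of cepstral coefficients (derived from the
#'   highest-order AR fit).
#' @param ar_method AR estimation method: `"burg"` (default) or
#'   `"yule-walker"`.
#' @param wavelet_levels Wavelet decomposition depth.
#' @param cc_literal If `TRUE`, use the printed-recursion variant of the
#'   cepstrum (see [cepstral_coefficients()]); default is the standard
#'   AR-cepstrum recursion.
#' @return An object of class `emg_feature_params`.
#' @export
feature_params <- function(ssc_threshold = 10, zc_threshold = 25,
                           ar_orders = c(5L, 6L), cc_order = 5L,
                           ar_method = c("burg", "yule-walker"),
                           wavelet_levels = 5L, cc_literal = FALSE) {
  ar_method <- match.arg(ar_method)
  stopifnot(ssc_threshold >= 0, zc_threshold >= 0,
            length(ar_orders) == 2L, cc_order <= max(ar_orders),
            wavelet_levels >= 1L)
  structure(
    list(
      ssc_threshold = ssc_threshold, zc_threshold = zc_threshold,
      ar_orders = as.integer(ar_orders), cc_order = as.integer(cc_order),
      ar_method = ar_method, wavelet_levels = as.integer(wavelet_levels),
      cc_literal = cc_literal
    ),
    class = "emg_feature_params"
  )
}

#' Feature-vector layout
#'
#' Ordered list of the 14 per-channel feature blocks and their dimensions:
#' MAV, VAR, RMS, SSC, ZC, WL, MNF, MDF contribute one dimension each, AR5
#' and CC five, AR6 and the three wavelet features six. Each channel thus
#' contributes 42 dimensions; the full vector is channel-major (all features
#' of channel 1, then channel 2, ...), giving 294 dimensions for 7 channels.
#'
#' @param channels Number of channels.
#' @return A tibble of class `emg_feature_layout` with columns `feature` and
#'   `dims`, carrying the channel count as an attribute.
#' @export
feature_layout <- function(channels = 7L) {
  out <- tibble::tibble(
    feature = c("MAV", "VAR", "RMS", "SSC", "ZC", "WL",
                "AR5", "AR6", "CC", "MNF", "MDF",
                "WTWL", "WTVAR", "WTMAV"),
    dims = c(1L, 1L, 1L, 1L, 1L, 1L, 5L, 6L, 5L, 1L, 1L, 6L, 6L, 6L)
  )
  attr(out, "channels") <- as.integer(channels)
  class(out) <- c("emg_feature_layout", class(out))
  out
}

#' @export
#' @rdname feature_layout
#' @param layout An [feature_layout()].
layout_total <- function(layout) {
  sum(layout$dims) * attr(layout, "channels")
}

#' Dimension indices of each feature group
#'
#' Maps each of the 14 feature names to the indices it occupies in the full
#' channel-major feature vector (across all channels). The 14 index sets
#' partition `1:layout_total(layout)`.
#'
#' @param layout An [feature_layout()].
#' @return Named list of integer vectors.
#' @export
feature_groups <- function(layout = feature_layout()) {
  channels <- attr(layout, "channels")
  per_channel <- sum(layout$dims)
  offsets <- cumsum(c(0L, layout$dims))[seq_len(nrow(layout))]
  groups <- lapply(seq_len(nrow(layout)), function(i) {
    within <- offsets[i] + seq_len(layout$dims[i])
    as.integer(outer(within, (seq_len(channels) - 1L) * per_channel, "+"))
  })
  names(groups) <- layout$feature
  groups
}

#' Locate one feature component in the full vector
#'
#' @param layout An [feature_layout()].
#' @param feature Feature name (e.g. `"AR6"`).
#' @param channel Channel number.
#' @param component Component within the feature block (default 1).
#' @return Integer index into the channel-major feature vector.
#' @export
layout_index <- function(layout, feature, channel, component = 1L) {
  i <- match(feature, layout$feature)
  if (is.na(i)) abort(sprintf("Unknown feature '%s'.", feature))
  stopifnot(component >= 1L, component <= layout$dims[i],
            channel >= 1L, channel <= attr(layout, "channels"))
  per_channel <- sum(layout$dims)
  offset <- cumsum(c(0L, layout$dims))[i]
  as.integer((channel - 1L) * per_channel + offset + component)
}

## ---- time-domain features ---------------------------------------------

#' Amplitude-based time-domain features
#'
#' Mean absolute value, uncentred variance, root mean square and waveform
#' length of one channel of one window. The variance deliberately omits mean
#' subtraction (`sum(x^2)/(N-1)`): band-passed EMG is zero-mean, and the
#' uncentred form is the convention in the myoelectric feature literature.
#'
#' @param x Numeric vector of window samples.
#' @return Named numeric vector `MAV`, `VAR`, `RMS`, `WL`.
#' @export
amplitude_features <- function(x) {
  n <- length(x)
  if (n < 2L) abort("Need at least 2 samples (variance uses N - 1).")
  ss <- sum(x^2)
  c(
    MAV = mean(abs(x)),
    VAR = ss / (n - 1),
    RMS = sqrt(ss / n),
    WL = sum(abs(diff(x)))
  )
}

#' Threshold-counting time-domain features
#'
#' Slope sign changes: indices `i` in `2..N-1` where
#' `(x[i]-x[i-1]) * (x[i]-x[i+1]) >= ssc_threshold`. Zero crossings: indices
#' `i` in `1..N-1` where `x[i]*x[i+1] < 0` and `|x[i]-x[i+1]| >=
#' zc_threshold`. The jump condition suppresses noise-induced crossings.
#'
#' @param x Numeric vector of window samples.
#' @param params An [feature_params()].
#' @return Named numeric vector `SSC`, `ZC`.
#' @export
threshold_features <- function(x, params = feature_params()) {
  n <- length(x)
  if (n < 3L) abort("Need at least 3 samples for SSC.")
  d <- diff(x)
  ssc <- sum(-d[-(n - 1L)] * d[-1L] >= params$ssc_threshold)
  zc <- sum(x[-n] * x[-1L] < 0 & abs(d) >= params$zc_threshold)
  c(SSC = ssc, ZC = zc)
}

## ---- autoregressive / cepstral features -------------------------------

# Burg recursion on every column of X (no demeaning). Returns p x K matrix of
# predictive coefficients a_1..a_p (x_t ~ sum a_i x_{t-i}). Zero-variance
# columns yield all-zero coefficients.
burg_mat <- function(X, p) {
  X <- as.matrix(X)
  K <- ncol(X)
  f <- X
  b <- X
  A <- matrix(0, p, K)
  for (m in seq_len(p)) {
    ff <- f[-1L, , drop = FALSE]
    bb <- b[-nrow(b), , drop = FALSE]
    den <- colSums(ff^2) + colSums(bb^2)
    k <- ifelse(den > 0, 2 * colSums(ff * bb) / den, 0)
    f <- ff - rep(k, each = nrow(ff)) * bb
    b <- bb - rep(k, each = nrow(bb)) * ff
    Aold <- A
    A[m, ] <- k
    if (m > 1L) {
      for (i in seq_len(m - 1L)) A[i, ] <- Aold[i, ] - k * Aold[m - i, ]
    }
  }
  A
}

#' Autoregressive model coefficients
#'
#' Fits `x[i] = sum_k a_k x[i-k] + e[i]` and returns `a_1..a_p`. The default
#' Burg estimator minimises forward plus backward prediction error and is
#' stable on short EMG windows; Yule-Walker is available as an alternative.
#' No mean is removed (the model has no intercept and band-passed EMG is
#' zero-mean).
#'
#' @param x Numeric vector, length > `order`.
#' @param order Model order `p`.
#' @param method `"burg"` or `"yule-walker"`.
#' @return Numeric vector of length `order`.
#' @export
ar_coefficients <- function(x, order, method = c("burg", "yule-walker")) {
  method <- match.arg(method)
  n <- length(x)
  if (n <= order) abort("Need more samples than the AR order.")
  if (all(x == x[1L])) {
    if (stats::var(x) == 0) {
      warn("Constant signal: AR coefficients undefined, returning zeros.")
      return(rep(0, order))
    }
  }
  if (method == "burg") {
    drop(burg_mat(matrix(x, ncol = 1L), order))
  } else {
    fit <- stats::ar.yw(x, aic = FALSE, order.max = order, demean = FALSE)
    coefs <- rep(0, order)
    coefs[seq_along(fit$ar)] <- fit$ar
    coefs
  }
}

# Cepstral recursion on columns of A (p x K of AR coefficients).
cepstral_mat <- function(A, k_max, literal = FALSE) {
  A <- as.matrix(A)
  K <- ncol(A)
  C <- matrix(0, k_max, K)
  C[1L, ] <- -A[1L, ]
  if (k_max >= 2L) {
    for (k in 2:k_max) {
      acc <- rep(0, K)
      for (i in seq_len(k - 1L)) {
        if (literal) {
          acc <- acc + (1 - i / k) * A[k, ] * C[k - 1L, ]
        } else {
          acc <- acc + (1 - i / k) * A[i, ] * C[k - i, ]
        }
      }
      C[k, ] <- -A[k, ] - acc
    }
  }
  C
}

#' Cepstral coefficients from AR coefficients
#'
#' Standard AR-cepstrum recursion: `c_1 = -a_1` and for `k >= 2`
#' `c_k = -a_k - sum_{i=1}^{k-1} (1 - i/k) a_i c_{k-i}`. A `literal`
#' variant replacing `a_i c_{k-i}` by `a_k c_{k-1}` (a transcription seen in
#' parts of the applied literature) is kept for comparison only.
#'
#' @param ar Numeric vector of AR coefficients `a_1..a_p`.
#' @param k_max Number of cepstral coefficients, `<= length(ar)`.
#' @param literal Use the non-standard printed recursion.
#' @return Numeric vector of length `k_max`.
#' @export
cepstral_coefficients <- function(ar, k_max = length(ar), literal = FALSE) {
  if (k_max > length(ar)) abort("`k_max` cannot exceed the AR order.")
  drop(cepstral_mat(matrix(ar, ncol = 1L), k_max, literal = literal))
}

## ---- spectral features ------------------------------------------------

# One-sided boxcar periodogram of the columns of X: |fft|^2 / N at bins
# 0 .. floor(N/2), bin width rate / N.
periodogram_mat <- function(X, sampling_rate) {
  X <- as.matrix(X)
  n <- nrow(X)
  P <- Mod(stats::mvfft(X))^2 / n
  keep <- seq_len(n %/% 2L + 1L)
  list(
    power = P[keep, , drop = FALSE],
    freq = (keep - 1L) * sampling_rate / n
  )
}

spectral_mat <- function(X, sampling_rate) {
  pg <- periodogram_mat(X, sampling_rate)
  tot <- colSums(pg$power)
  if (any(tot <= 0)) {
    abort("Zero-power window: spectral moments are undefined.")
  }
  mnf <- colSums(pg$freq * pg$power) / tot
  cs <- apply(pg$power, 2L, cumsum)
  idx <- colSums(cs < rep(tot / 2, each = nrow(cs))) + 1L
  rbind(MNF = mnf, MDF = pg$freq[idx])
}

#' Mean and median frequency of the window spectrum
#'
#' Power spectrum taken as the one-sided boxcar periodogram of the raw
#' window (no detrending), bin width `sampling_rate / N`. MNF is the
#' power-weighted mean of the bin frequencies; MDF is the frequency of the
#' first bin at which cumulative power reaches half of the total. Half of
#' the total spectral power is returned alongside, since the median is
#' defined through it.
#'
#' @param x Numeric vector of window samples (nonzero power).
#' @param sampling_rate Sampling rate in Hz.
#' @return Named numeric vector `MNF`, `MDF` (Hz) and `half_total_power`.
#' @export
spectral_features <- function(x, sampling_rate) {
  X <- matrix(as.numeric(x), ncol = 1L)
  sp <- spectral_mat(X, sampling_rate)
  pg <- periodogram_mat(X, sampling_rate)
  c(MNF = unname(sp["MNF", 1L]), MDF = unname(sp["MDF", 1L]),
    half_total_power = sum(pg$power) / 2)
}

## ---- wavelet features -------------------------------------------------

wavelet_mat <- function(X, levels = 5L) {
  bands <- dwt_db2_mat(X, levels)
  order <- c(paste0("cA", levels), paste0("cD", seq_len(levels)))
  bands <- bands[order]
  wl <- do.call(rbind, lapply(bands, function(b) {
    colSums(abs(b[-1L, , drop = FALSE] - b[-nrow(b), , drop = FALSE]))
  }))
  vr <- do.call(rbind, lapply(bands, function(b) colSums(b^2) / (nrow(b) - 1)))
  mav <- do.call(rbind, lapply(bands, function(b) colMeans(abs(b))))
  rownames(wl) <- paste0("WTWL_", order)
  rownames(vr) <- paste0("WTVAR_", order)
  rownames(mav) <- paste0("WTMAV_", order)
  rbind(wl, vr, mav)
}

#' Wavelet-domain features of one channel
#'
#' Five-level db2 decomposition of the window; on each of the six coefficient
#' vectors (cA5, cD1..cD5) the waveform length, uncentred variance and mean
#' absolute value are computed with the same formulas as their time-domain
#' counterparts. Ordering is feature-major: WTWL over the six bands, then
#' WTVAR, then WTMAV.
#'
#' @param x Numeric vector of window samples.
#' @param params An [feature_params()].
#' @return Named numeric vector of length 18.
#' @export
wavelet_features <- function(x, params = feature_params()) {
  m <- wavelet_mat(matrix(as.numeric(x), ncol = 1L), params$wavelet_levels)
  setNames(drop(m), rownames(m))
}

## ---- full vector assembly ---------------------------------------------

# 42 x W feature block for one channel: X is N x W (windows in columns).
channel_feature_block <- function(X, sampling_rate, params) {
  n <- nrow(X)
  ss <- colSums(X^2)
  d <- X[-1L, , drop = FALSE] - X[-n, , drop = FALSE]
  mav <- colMeans(abs(X))
  vr <- ss / (n - 1)
  rms <- sqrt(ss / n)
  ssc <- colSums(-d[-(n - 1L), , drop = FALSE] * d[-1L, , drop = FALSE] >=
                   params$ssc_threshold)
  zc <- colSums(X[-n, , drop = FALSE] * X[-1L, , drop = FALSE] < 0 &
                  abs(d) >= params$zc_threshold)
  wl <- colSums(abs(d))
  p_lo <- min(params$ar_orders)
  p_hi <- max(params$ar_orders)
  if (params$ar_method == "burg") {
    ar_lo <- burg_mat(X, p_lo)
    ar_hi <- burg_mat(X, p_hi)
  } else {
    ar_lo <- vapply(seq_len(ncol(X)), function(j)
      ar_coefficients(X[, j], p_lo, method = "yule-walker"), numeric(p_lo))
    ar_hi <- vapply(seq_len(ncol(X)), function(j)
      ar_coefficients(X[, j], p_hi, method = "yule-walker"), numeric(p_hi))
    ar_lo <- matrix(ar_lo, nrow = p_lo)
    ar_hi <- matrix(ar_hi, nrow = p_hi)
  }
  cc <- cepstral_mat(ar_hi, params$cc_order, literal = params$cc_literal)
  sp <- spectral_mat(X, sampling_rate)
  wt <- wavelet_mat(X, params$wavelet_levels)
  rownames(ar_lo) <- paste0("AR", p_lo, "_", seq_len(p_lo))
  rownames(ar_hi) <- paste0("AR", p_hi, "_", seq_len(p_hi))
  rownames(cc) <- paste0("CC_", seq_len(params$cc_order))
  rbind(
    MAV = mav, VAR = vr, RMS = rms, SSC = ssc, ZC = zc, WL = wl,
    ar_lo, ar_hi, cc, sp, wt
  )
}

#' Extract the full feature vector of one window
#'
#' Computes all 14 features on every channel and concatenates them
#' channel-major (all 42 features of channel 1, then channel 2, ...). For a
#' 7-channel window this yields a 294-dimensional vector.
#'
#' @param samples Channels-by-N numeric matrix (one window), or an
#'   `emg_trial` used whole.
#' @param sampling_rate Sampling rate in Hz.
#' @param params An [feature_params()].
#' @return Named numeric vector of length `42 * channels`.
#' @export
extract_feature_vector <- function(samples, sampling_rate = 1500,
                                   params = feature_params()) {
  if (inherits(samples, "emg_trial")) {
    sampling_rate <- samples$sampling_rate
    samples <- samples$samples
  }
  samples <- as.matrix(samples)
  blocks <- lapply(seq_len(nrow(samples)), function(c) {
    b <- channel_feature_block(matrix(samples[c, ], ncol = 1L),
                               sampling_rate, params)
    setNames(drop(b), paste0("ch", c, "_", rownames(b)))
  })
  unlist(blocks)
}

#' Extract features for a table of windows
#'
#' Vectorised feature extraction over all windows of a segmented session.
#' Returns one row per window with the channel-major feature dimensions in
#' columns `dim_0001 ...`, followed by the class label and provenance.
#'
#' @param windows Tibble from [segment_trial()]/[segment_session()] with a
#'   `samples` list-column.
#' @param sampling_rate Sampling rate in Hz.
#' @param params An [feature_params()].
#' @return A tibble with `42 * channels` feature columns plus `label`,
#'   `subject`, `day`, `trial`, `window`.
#' @export
extract_features <- function(windows, sampling_rate = 1500,
                             params = feature_params()) {
  stopifnot(is.data.frame(windows), "samples" %in% names(windows))
  w <- nrow(windows)
  if (w == 0L) abort("No windows to extract features from.")
  first <- windows$samples[[1L]]
  channels <- nrow(first)
  n <- ncol(first)
  blocks <- lapply(seq_len(channels), function(c) {
    X <- vapply(windows$samples, function(m) m[c, ], numeric(n))
    channel_feature_block(matrix(X, nrow = n), sampling_rate, params)
  })
  mat <- t(do.call(rbind, blocks))
  colnames(mat) <- sprintf("dim_%04d", seq_len(ncol(mat)))
  dplyr::bind_cols(
    tibble::as_tibble(mat),
    tibble::tibble(
      label = windows$motion,
      subject = windows$subject,
      day = windows$day,
      trial = windows$trial,
      window = windows$window
    )
  )
}

#' Split a feature table into matrix and labels
#'
#' @param features Feature tibble from [extract_features()] (columns
#'   `dim_*` plus metadata).
#' @return List with `x` (numeric matrix) and `y` (factor of labels).
#' @export
feature_matrix <- function(features) {
  dims <- grep("^dim_", names(features), value = TRUE)
  x <- as.matrix(features[, dims])
  y <- if ("label" %in% names(features)) factor(features$label) else NULL
  list(x = x, y = y)
}
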