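# Deterministic seed derivation (linear congruential mixing, exact in
# doubles), so any trial can be regenerated independently of the others.
derive_seed <- function(master, ...) {
  h <- as.numeric(master) %% 2147483647
  for (v in c(...)) {
    h <- (h * 1664525 + 1013904223 + as.numeric(v)) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Shape white Gaussian noise to a frequency band via FFT filtering.
# H is a Gaussian bump centred at `center` with standard deviation
# `width / 2`, hard-limited to [band_lo, band_hi]; `center = NULL` gives a
# flat passband. Output is scaled to unit RMS.
band_noise <- function(n, sampling_rate, center = NULL, width = NULL,
                       band_lo = 20, band_hi = 450) {
  z <- rnorm(n)
  f <- (seq_len(n) - 1L) * sampling_rate / n
  f <- pmin(f, sampling_rate - f) # two-sided frequency magnitude
  h <- as.numeric(f >= band_lo & f <= band_hi)
  if (!is.null(center)) {
    h <- h * exp(-(f - center)^2 / (2 * (width / 2)^2))
  }
  y <- Re(stats::fft(stats::fft(z) * h, inverse = TRUE)) / n
  y / sqrt(mean(y^2))
}

# Slow multiplicative activation wander (lowpass-shaped, unit sd).
slow_modulation <- function(n, sampling_rate, cutoff_hz = 1) {
  z <- rnorm(n)
  f <- (seq_len(n) - 1L) * sampling_rate / n
  f <- pmin(f, sampling_rate - f)
  h <- exp(-(f / cutoff_hz)^2)
  y <- Re(stats::fft(stats::fft(z) * h, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Generate a synthetic subject profile
#'
#' Draws the per-motion, per-channel activation pattern of one simulated
#' subject. Each motion strongly activates 2-4 of the 7 channels (the
#' remainder idle at a low level), mimicking the muscle synergies of
#' shoulder/elbow motions; patterns are redrawn until no two motions
#' correlate above 0.95. Each channel gets its own spectral centre
#' (60-150 Hz) and bandwidth, all inside the 20-450 Hz acquisition band.
#' The additive noise floor sits 20 dB below the weakest strong activation.
#'
#' @param seed Integer seed; identical seeds give identical profiles.
#' @param n_motions Number of motion classes.
#' @param channels Number of electrode channels.
#' @param motions Motion labels (length `n_motions`).
#' @return An object of class `emg_subject_profile` with fields
#'   `amplitude` (`n_motions x channels`), `center_freq`, `bandwidth`,
#'   `noise_floor`, `motions`, `seed`.
#' @export
generate_subject_profile <- function(seed, n_motions = 11L, channels = 7L,
                                     motions = emg_motion_labels()) {
  stopifnot(length(motions) == n_motions, channels >= 7L)
  with_seed(seed, {
    draw_pattern <- function(primary, secondary) {
      row <- runif(channels, 5, 12)
      row[secondary] <- runif(length(secondary), 15, 35)
      row[primary] <- runif(length(primary), 50, 85)
      row
    }
    # Muscle synergies on the 7 channels (anterior/middle/posterior deltoid,
    # biceps, triceps, brachioradialis, flexor carpi radialis): the three
    # shoulder motions load the deltoids, the two elbow motions the upper-arm
    # and forearm flexors/extensors. Compound motions superpose their
    # components at slightly reduced drive, so classes sharing a component
    # are genuinely confusable, as with real shoulder/elbow EMG.
    basics <- list(
      SF  = draw_pattern(1L, c(2L, 4L)),
      SA  = draw_pattern(2L, c(1L, 3L)),
      SPF = draw_pattern(3L, c(2L, 5L)),
      EF  = draw_pattern(c(4L, 6L), 7L),
      EE  = draw_pattern(5L, 6L)
    )
    compose <- function(shoulder, elbow) {
      0.85 * (basics[[shoulder]] + basics[[elbow]]) *
        rlnorm(channels, 0, 0.05)
    }
    patterns <- c(basics, list(
      SFEF = compose("SF", "EF"), SFEE = compose("SF", "EE"),
      SAEF = compose("SA", "EF"), SAEE = compose("SA", "EE"),
      SPFEF = compose("SPF", "EF"), SPFEE = compose("SPF", "EE")
    ))
    amp <- do.call(rbind, patterns)[seq_len(n_motions), , drop = FALSE]
    rownames(amp) <- motions
    cors <- stats::cor(t(amp))
    if (max(cors[upper.tri(cors)]) >= 0.95) {
      abort("Could not draw sufficiently distinct motion patterns.")
    }
    structure(
      list(
        amplitude = amp,
        center_freq = runif(channels, 60, 150),
        bandwidth = runif(channels, 50, 90),
        noise_floor = 0.1 * min(amp[amp >= 50]),
        motions = motions,
        seed = as.integer(seed)
      ),
      class = "emg_subject_profile"
    )
  })
}

#' Per-day electrode-shift model
#'
#' Simulates the effect of re-donning the electrodes on a later day: each
#' channel's gain is perturbed (lognormal, sd `0.25 * magnitude`), channels
#' leak into their neighbours through a near-identity row-stochastic mixing
#' matrix (off-diagonal mass `0.15 * magnitude`), and each channel's
#' spectral centre drifts (normal, sd `10 * magnitude` Hz). Day 1 is always
#' the identity, and `magnitude = 0` makes every day identically
#' distributed.
#'
#' @param day Session day; day 1 returns the identity shift.
#' @param magnitude Shift magnitude scalar in `[0, 1]`.
#' @param seed Integer seed.
#' @param channels Number of channels.
#' @return An object of class `emg_shift_model` with `gain`, `mix`,
#'   `freq_offset`, `magnitude`, `day`.
#' @export
shift_model <- function(day, magnitude = 1, seed = 1L, channels = 7L) {
  stopifnot(magnitude >= 0, magnitude <= 1)
  if (day == 1L || magnitude == 0) {
    return(structure(
      list(gain = rep(1, channels), mix = diag(channels),
           freq_offset = rep(0, channels),
           magnitude = magnitude, day = as.integer(day)),
      class = "emg_shift_model"
    ))
  }
  with_seed(seed, {
    gain <- rlnorm(channels, 0, 0.25 * magnitude)
    kappa <- 0.15 * magnitude
    mix <- diag(1 - kappa, channels)
    for (r in seq_len(channels)) {
      off <- runif(channels - 1L)
      mix[r, -r] <- off / sum(off) * kappa
    }
    structure(
      list(gain = gain, mix = mix,
           freq_offset = rnorm(channels, 0, 10 * magnitude),
           magnitude = magnitude, day = as.integer(day)),
      class = "emg_shift_model"
    )
  })
}

#' Synthesize one EMG trial
#'
#' Phenomenological surface-EMG model: per channel, band-limited Gaussian
#' noise (Gaussian spectral bump at the channel's centre frequency, shifted
#' by the day's spectral drift) is amplitude-modulated by the motion's
#' activation level, a trial-specific lognormal jitter, an onset/offset
#' ramp and a slow within-trial wander; a flat-band noise floor is added
#' and the channels are mixed by the day's crosstalk matrix. Activation
#' amplitudes are calibrated so typical sample magnitudes are of order
#' 10-100 units, which keeps the SSC/ZC counting thresholds (10 and 25)
#' meaningful.
#'
#' @param profile An [generate_subject_profile()].
#' @param shift An [shift_model()] for the trial's day.
#' @param motion Motion label (must appear in `profile$motions`).
#' @param trial_index Repetition index.
#' @param seed Integer seed for this trial.
#' @param duration_s Trial length in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @param subject Subject identifier attached to the trial.
#' @return An [emg_trial()] of shape `channels x (duration_s * rate)`.
#' @export
synthesize_trial <- function(profile, shift, motion, trial_index = 1L,
                             seed = 1L, duration_s = 7, sampling_rate = 1500,
                             subject = "S1") {
  m <- match(motion, profile$motions)
  if (is.na(m)) abort(sprintf("Unknown motion '%s'.", motion))
  channels <- ncol(profile$amplitude)
  n <- as.integer(round(duration_s * sampling_rate))
  with_seed(seed, {
    ramp_n <- as.integer(round(0.75 * sampling_rate))
    env <- rep(1, n)
    env[seq_len(ramp_n)] <- seq(0, 1, length.out = ramp_n)
    env[(n - ramp_n + 1L):n] <- seq(1, 0, length.out = ramp_n)
    x <- matrix(0, channels, n)
    for (c in seq_len(channels)) {
      center <- min(max(profile$center_freq[c] + shift$freq_offset[c], 30), 200)
      carrier <- band_noise(n, sampling_rate, center, profile$bandwidth[c])
      wander <- pmax(1 + 0.4 * slow_modulation(n, sampling_rate, cutoff_hz = 2), 0.1)
      jitter <- rlnorm(1, 0, 0.15)
      amp <- profile$amplitude[m, c] * shift$gain[c] * jitter
      floor_noise <- profile$noise_floor * band_noise(n, sampling_rate)
      x[c, ] <- amp * env * wander * carrier + floor_noise
    }
    emg_trial(
      shift$mix %*% x, sampling_rate, motion,
      trial_index = trial_index, day = shift$day, subject = subject
    )
  })
}

#' Benchmark configuration
#'
#' The study conditions of the multi-day protocol: 12 subjects recorded on
#' 5 consecutive days, 11 motions repeated 5 times per day in 7-s trials at
#' 1500 Hz over 7 channels, of which the central 5 s enter the analysis.
#' `shift_magnitude` scales the day-to-day electrode-shift model (1 = full
#' shift, 0 = no drift at all).
#'
#' @param n_subjects,n_days,n_motions,n_trials Protocol counts.
#' @param trial_s,keep_central_s,sampling_rate,channels Signal geometry.
#' @param shift_magnitude Electrode-shift magnitude in `[0, 1]`.
#' @param master_seed Seed from which every per-subject/per-trial seed is
#'   derived.
#' @return An object of class `emg_benchmark_config`.
#' @export
benchmark_config <- function(n_subjects = 12L, n_days = 5L, n_motions = 11L,
                             n_trials = 5L, trial_s = 7, keep_central_s = 5,
                             sampling_rate = 1500, channels = 7L,
                             shift_magnitude = 1, master_seed = 1L) {
  stopifnot(n_subjects >= 1L, n_days >= 1L, n_motions >= 2L, n_trials >= 1L,
            trial_s >= keep_central_s)
  structure(
    list(
      n_subjects = as.integer(n_subjects), n_days = as.integer(n_days),
      n_motions = as.integer(n_motions), n_trials = as.integer(n_trials),
      trial_s = trial_s, keep_central_s = keep_central_s,
      sampling_rate = sampling_rate, channels = as.integer(channels),
      shift_magnitude = shift_magnitude,
      master_seed = as.integer(master_seed)
    ),
    class = "emg_benchmark_config"
  )
}

#' Generate the full multi-day benchmark data set
#'
#' One subject profile per subject, one shift model per subject-day (day 1
#' is the identity), and `n_motions * n_trials` trials per subject-day. All
#' randomness derives deterministically from `master_seed`, per trial, so
#' any subset regenerates identically.
#'
#' @param config An [benchmark_config()].
#' @param subjects Optional subset of subject indices to generate.
#' @param days Optional subset of days to generate.
#' @return A tibble with columns `subject`, `day`, `motion`, `trial` and a
#'   `recording` list-column of [emg_trial()] objects.
#' @export
generate_benchmark <- function(config = benchmark_config(),
                               subjects = seq_len(config$n_subjects),
                               days = seq_len(config$n_days)) {
  motions <- emg_motion_labels()[seq_len(config$n_motions)]
  rows <- list()
  for (s in subjects) {
    profile <- generate_subject_profile(
      derive_seed(config$master_seed, s, 101),
      n_motions = config$n_motions, channels = config$channels,
      motions = motions
    )
    for (d in days) {
      shift <- shift_model(
        d, magnitude = config$shift_magnitude,
        seed = derive_seed(config$master_seed, s, d, 202),
        channels = config$channels
      )
      for (m in seq_along(motions)) {
        for (tr in seq_len(config$n_trials)) {
          rec <- synthesize_trial(
            profile, shift, motions[m], trial_index = tr,
            seed = derive_seed(config$master_seed, s, d, m, tr),
            duration_s = config$trial_s,
            sampling_rate = config$sampling_rate,
            subject = paste0("S", s)
          )
          rows[[length(rows) + 1L]] <- tibble::tibble(
            subject = paste0("S", s), day = d, motion = motions[m],
            trial = tr, recording = list(rec)
          )
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}
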