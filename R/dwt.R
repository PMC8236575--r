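# Daubechies-2 analysis filters (4 taps), standard orthonormal normalisation.
DB2_DEC_LO <- c(-0.12940952255092145, 0.22414386804185735,
                0.83651630373780790, 0.48296291314469025)
DB2_DEC_HI <- c(-0.48296291314469025, 0.83651630373780790,
                -0.22414386804185735, -0.12940952255092145)

# One analysis step on the columns of X with half-sample symmetric padding
# (edge sample repeated), full convolution, downsampled by two. Output length
# floor((n + f - 1) / 2) for filter length f = 4.
dwt_step_mat <- function(X, filt) {
  n <- nrow(X)
  p <- length(filt) - 1L
  if (n < p) abort("Signal too short for one db2 analysis step.")
  XP <- rbind(
    X[p:1, , drop = FALSE],
    X,
    X[n:(n - p + 1L), , drop = FALSE]
  )
  L <- (n + p) %/% 2L
  out <- matrix(0, L, ncol(X))
  rows <- 2L * seq_len(L) + p
  for (j in 0:p) {
    out <- out + filt[j + 1L] * XP[rows - j, , drop = FALSE]
  }
  out
}

# Multilevel decomposition of every column of X. Returns the level-`levels`
# approximation and all detail bands, in the order cA<levels>, cD1 .. cD<levels>.
dwt_db2_mat <- function(X, levels = 5L) {
  X <- as.matrix(X)
  n <- nrow(X)
  min_n <- 3L * 2L^levels
  if (n < min_n) {
    abort(sprintf(
      "Signal length %d too short for a %d-level db2 decomposition (minimum %d samples).",
      n, levels, min_n
    ))
  }
  details <- vector("list", levels)
  a <- X
  for (lev in seq_len(levels)) {
    d <- dwt_step_mat(a, DB2_DEC_HI)
    a <- dwt_step_mat(a, DB2_DEC_LO)
    details[[lev]] <- d
  }
  out <- c(list(a), details)
  names(out) <- c(paste0("cA", levels), paste0("cD", seq_len(levels)))
  out
}

#' Multilevel db2 wavelet decomposition
#'
#' Five-level (by default) discrete wavelet transform with the Daubechies-2
#' wavelet and symmetric boundary padding. Returns the final approximation
#' band and every detail band; these six coefficient vectors feed the
#' wavelet-domain EMG features (WTWL, WTVAR, WTMAV).
#'
#' @param x Numeric vector (one channel of one window).
#' @param levels Number of decomposition levels (default 5).
#' @return Named list `cA<levels>`, `cD1` ... `cD<levels>` of coefficient
#'   vectors.
#' @export
dwt_db2 <- function(x, levels = 5L) {
  lapply(dwt_db2_mat(matrix(as.numeric(x), ncol = 1L), levels), drop)
}
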