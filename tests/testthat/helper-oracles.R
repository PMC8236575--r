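# Independent slow-path oracles used to check the vectorised implementations.
# These deliberately share no code with the package internals.

oracle_amplitude <- function(x) {
  n <- length(x)
  mav <- 0
  ss <- 0
  wl <- 0
  for (i in seq_len(n)) {
    mav <- mav + abs(x[i]) / n
    ss <- ss + x[i]^2
  }
  for (i in seq_len(n - 1)) wl <- wl + abs(x[i + 1] - x[i])
  c(MAV = mav, VAR = ss / (n - 1), RMS = sqrt(ss / n), WL = wl)
}

oracle_threshold <- function(x, ssc_thr, zc_thr) {
  n <- length(x)
  ssc <- 0
  zc <- 0
  for (i in 2:(n - 1)) {
    if ((x[i] - x[i - 1]) * (x[i] - x[i + 1]) >= ssc_thr) ssc <- ssc + 1
  }
  for (i in 1:(n - 1)) {
    if (x[i] * x[i + 1] < 0 && abs(x[i] - x[i + 1]) >= zc_thr) zc <- zc + 1
  }
  c(SSC = ssc, ZC = zc)
}

# Median frequency by explicit cumulative scan over the one-sided boxcar
# periodogram.
oracle_mdf <- function(x, rate) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  p <- p[1:(n %/% 2 + 1)]
  freq <- (seq_along(p) - 1) * rate / n
  half <- sum(p) / 2
  acc <- 0
  for (i in seq_along(p)) {
    acc <- acc + p[i]
    if (acc >= half) return(freq[i])
  }
  freq[length(freq)]
}

# Naive db2 analysis step: explicit convolution loop over the padded signal
# (half-sample symmetric extension), downsampled by two.
oracle_dwt_step <- function(x, filt) {
  n <- length(x)
  p <- length(filt) - 1
  xp <- c(rev(x[1:p]), x, rev(x[(n - p + 1):n]))
  len <- (n + p) %/% 2
  out <- numeric(len)
  for (i in seq_len(len)) {
    acc <- 0
    for (j in 0:p) acc <- acc + filt[j + 1] * xp[2 * i + p - j]
    out[i] <- acc
  }
  out
}

oracle_dwt <- function(x, levels = 5) {
  lo <- c(-0.12940952255092145, 0.22414386804185735,
          0.83651630373780790, 0.48296291314469025)
  hi <- c(-0.48296291314469025, 0.83651630373780790,
          -0.22414386804185735, -0.12940952255092145)
  out <- list()
  a <- x
  for (lev in seq_len(levels)) {
    out[[paste0("cD", lev)]] <- oracle_dwt_step(a, hi)
    a <- oracle_dwt_step(a, lo)
  }
  out[[paste0("cA", levels)]] <- a
  out
}

# Loop-based scatter matrices straight from the defining sums.
oracle_scatter <- function(x, labels) {
  labels <- factor(labels)
  m <- nlevels(labels)
  d <- ncol(x)
  means <- matrix(0, m, d)
  sw <- matrix(0, d, d)
  for (i in seq_len(m)) {
    xi <- x[labels == levels(labels)[i], , drop = FALSE]
    means[i, ] <- colMeans(xi)
    si <- matrix(0, d, d)
    for (r in seq_len(nrow(xi))) {
      v <- xi[r, ] - means[i, ]
      si <- si + outer(v, v)
    }
    sw <- sw + si / nrow(xi) / m
  }
  u0 <- colMeans(means)
  sb <- matrix(0, d, d)
  for (i in seq_len(m)) {
    v <- means[i, ] - u0
    sb <- sb + outer(v, v) / m
  }
  list(Sw = sw, Sb = sb, Sm = sw + sb)
}

oracle_j3 <- function(x, labels) {
  s <- oracle_scatter(x, labels)
  sum(diag(solve(s$Sw) %*% s$Sm))
}

# Exhaustive greedy forward selection over named column groups, maximising
# J3 exactly as defined; used to check sfs_select on tiny problems.
oracle_greedy_sfs <- function(x, labels, groups, tol = 1e-9) {
  selected <- character()
  dims <- integer()
  best_val <- -Inf
  remaining <- names(groups)
  repeat {
    if (length(remaining) == 0) break
    vals <- sapply(remaining, function(g) {
      oracle_j3(x[, c(dims, groups[[g]]), drop = FALSE], labels)
    })
    k <- which.max(vals)
    if (vals[k] <= best_val + tol) break
    selected <- c(selected, remaining[k])
    dims <- c(dims, groups[[remaining[k]]])
    best_val <- vals[k]
    remaining <- setdiff(remaining, remaining[k])
  }
  list(groups = selected, dims = dims)
}

# Window count by explicit enumeration.
oracle_n_windows <- function(l, n, step) {
  count <- 0
  start <- 1
  while (start + n - 1 <= l) {
    count <- count + 1
    start <- start + step
  }
  count
}
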