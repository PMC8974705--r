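# Shared fixture builders; everything is generated in code at test time.

# recording holding given per-channel signals (list or matrix)
rec_of <- function(x, fs = 1000, montage = "monopolar", grid = NULL) {
  if (is.list(x)) x <- do.call(rbind, x)
  emg_recording(x, fs, montage, grid = grid)
}

# sine wave sampled at fs
sine <- function(f, fs, n, amp = 1, phase = 0) {
  amp * sin(2 * pi * f * (0:(n - 1)) / fs + phase)
}

# amplitude of a (near-)sinusoid from the RMS of its central section,
# avoiding sample-phase quantization of max()
sine_amp <- function(x, trim = 0.2) {
  k <- floor(length(x) * trim)
  sqrt(2 * mean(x[(k + 1):(length(x) - k)]^2))
}

# synthetic GRF: half-sine stance bumps with known event samples (1-based)
make_grf <- function(n_strides = 5, stride_s = 1, stance_frac = 0.6,
                     fs = 1000, peak = 1500) {
  n <- n_strides * stride_s * fs
  force <- numeric(n)
  hs <- round((seq_len(n_strides) - 1) * stride_s * fs) + 1L
  to <- hs + round(stance_frac * stride_s * fs)
  for (k in seq_len(n_strides)) {
    idx <- hs[k]:(to[k] - 1L)
    idx <- idx[idx <= n]
    force[idx] <- peak * sin(pi * (idx - hs[k]) / (to[k] - hs[k]))
  }
  list(grf = structure(list(force = force, fs = fs), class = "grf_series"),
       hs = hs, to = to)
}

# small default simulation shared by the slower tests
small_sim <- function(seed = 7, n_strides = 6, ...) {
  simulate_hdemg(sim_config(n_strides = n_strides, seed = seed, ...))
}

# independent brute-force Benjamini-Hochberg step-up (the oracle):
# adjusted value for rank i is min over j >= i of p_(j) * m / j, capped at 1
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    ranks <- i:m
    adj[o[i]] <- min(pmin(p[o[ranks]] * m / ranks, 1))
  }
  adj
}

# independent iterative z-score screening (same rule, separate code path)
screen_brute <- function(x, z = 3, max_iter = 8) {
  lr <- log(sqrt(rowMeans(x^2)))
  ku <- apply(x, 1, function(v) {
    v <- v - mean(v); m2 <- mean(v^2)
    if (m2 <= 0) 0 else mean(v^4) / m2^2 - 3
  })
  valid <- rep(TRUE, nrow(x))
  for (it in seq_len(max_iter)) {
    z1 <- if (sd(lr[valid]) < 1e-12) rep(0, length(lr)) else
      (lr - mean(lr[valid])) / sd(lr[valid])
    z2 <- if (sd(ku[valid]) < 1e-12) rep(0, length(ku)) else
      (ku - mean(ku[valid])) / sd(ku[valid])
    bad <- valid & (abs(z1) > z | abs(z2) > z)
    if (!any(bad)) break
    valid[bad] <- FALSE
  }
  which(!valid)
}

# band amplitude sum of a vector in (lo, hi]
band_amp_sum <- function(x, fs, lo, hi) {
  sp <- amplitude_spectrum(x, fs)
  sum(sp$amplitude[sp$freq > lo & sp$freq <= hi])
}
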