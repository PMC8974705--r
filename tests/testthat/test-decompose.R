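test_that("PCA recovers a dominant shared source and conserves variance", {
  set.seed(8)
  n <- 4000
  s <- sine(40, 1000, n)
  x <- rbind(s + rnorm(n, sd = 1e-3), s + rnorm(n, sd = 1e-3))
  cs <- pca_decompose(rec_of(x))

  # hand oracle: eigenvalues of the 2x2 covariance
  cv <- stats::cov(t(x - rowMeans(x)))
  lam <- eigen(cv, symmetric = TRUE)$values
  expect_equal(cs$scores, lam / sum(lam), tolerance = 1e-10)
  expect_gt(cs$scores[1], 0.99)
  expect_gt(abs(cor(cs$sources[1, ], s)), 0.999)

  # orthogonality and trace conservation on a larger random problem
  set.seed(9)
  x2 <- matrix(rnorm(16 * 3000), 16) * sqrt(1:16)
  cs2 <- pca_decompose(rec_of(x2))
  cc <- cor(t(cs2$sources))
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  expect_equal(sum(apply(cs2$sources, 1, var)),
               sum(apply(x2, 1, var)), tolerance = 1e-10)
  expect_true(all(diff(cs2$scores) <= 1e-12))
  expect_equal(sum(cs2$scores), 1, tolerance = 1e-12)
})

test_that("CCA orders components by lag autocorrelation", {
  set.seed(10)
  n <- 5000
  # one slow sine + white noise sources mixed across 8 channels
  s_slow <- sine(2, 1000, n)
  src <- rbind(s_slow, matrix(rnorm(7 * n), 7))
  mix <- matrix(rnorm(64), 8)
  cs <- cca_decompose(rec_of(mix %*% src))
  expect_gt(abs(cor(cs$sources[1, ], s_slow)), 0.95)
  expect_gt(cs$scores[1], cs$scores[8])
  expect_true(all(diff(cs$scores) <= 1e-12))
  expect_true(all(abs(cs$scores) <= 1))

  # analytic lag-1 autocorrelation of a sinusoid: cos(2 pi f / fs)
  f0 <- 30; fs <- 1000
  pure <- sine(f0, fs, n)
  two <- rbind(pure + rnorm(n, sd = 1e-4), pure + rnorm(n, sd = 1e-4))
  cs2 <- cca_decompose(rec_of(two))
  expect_equal(cs2$scores[1], cos(2 * pi * f0 / fs), tolerance = 0.01)

  # scores equal the empirical lag-1 autocorrelations of the sources
  for (i in seq_len(nrow(cs$sources))) {
    s <- cs$sources[i, ]
    expect_equal(cs$scores[i], cor(s[-n], s[-1]), tolerance = 1e-6)
  }
})

test_that("PCA and CCA reconstructions are faithful round-trips", {
  set.seed(12)
  rec <- rec_of(matrix(rnorm(16 * 2000), 16) * 10 + 5)
  for (m in c("pca", "cca")) {
    cs <- if (m == "pca") pca_decompose(rec) else cca_decompose(rec)
    back <- reconstruct(cs, rec = rec)
    relerr <- max(abs(back$data - rec$data)) / max(abs(rec$data))
    expect_lt(relerr, 1e-8)
  }

  # zeroing one component removes exactly its rank-one contribution
  cs <- pca_decompose(rec)
  cl <- cs$sources
  cl[3, ] <- 0
  back3 <- reconstruct(cs, cl, rec)
  delta <- rec$data - back3$data
  expected <- cs$mixing[, 3, drop = FALSE] %*% cs$sources[3, , drop = FALSE]
  expect_equal(delta, expected, tolerance = 1e-10)

  expect_error(reconstruct(cs, cl[1:2, ], rec), "shape")
})

test_that("component spectra satisfy Parseval and locate sinusoid peaks", {
  set.seed(13)
  rec <- rec_of(rbind(sine(50, 1000, 2000), rnorm(2000), 0))
  cs <- pca_decompose(rec)
  cs$sources <- rec$data  # inspect raw rows directly through the same API
  sp <- component_spectra(cs, 1000)
  expect_equal(sp$freq[which.max(sp$amplitude[1, ])], 50)
  expect_equal(max(sp$amplitude[3, ]), 0)
  # Parseval under the one-sided amplitude scaling
  n <- 2000
  x <- rec$data[2, ]
  X <- fft(x)
  expect_equal(sum(Mod(X)^2) / n, sum(x^2), tolerance = 1e-8)
})

test_that("artifact components are flagged by in-band amplitude fraction", {
  set.seed(14)
  n <- 4000
  src <- matrix(rnorm(10 * n), 10)
  src[4, ] <- 40 * sine(2, 1000, n) + rnorm(n, sd = 0.1)
  mix <- matrix(rnorm(100), 10)
  diag(mix) <- diag(mix) + 2
  cs <- cca_decompose(rec_of(mix %*% src))
  rpt <- flag_components(cs)
  # the slow high-amplitude component ranks first under CCA and is flagged
  expect_true(1 %in% rpt$flagged)
  expect_gt(rpt$band_fraction[1], 0.8)
  expect_lt(max(rpt$band_fraction[-1]), 0.1)

  # white-noise-only components: flags are rare (band fraction ~ 20/500)
  set.seed(15)
  flags <- replicate(10, {
    cs0 <- pca_decompose(rec_of(matrix(rnorm(10 * 2000), 10)))
    length(flag_components(cs0)$flagged)
  })
  expect_lt(mean(flags), 2)

  # fewer than 3 components: degenerate, nothing flagged
  cs2 <- pca_decompose(rec_of(matrix(rnorm(2 * 1000), 2)))
  expect_length(flag_components(cs2)$flagged, 0L)
})

test_that("spectral cancellation caps in-band bins and preserves the rest", {
  fs <- 1000; n <- 2000
  half <- n / 2 + 1

  # zero amplitude inside the band: bit-identical within FFT round-trip
  x <- sine(100, fs, n)
  out <- spectral_cancel(x, fs, c(0, 20), reference = rep(0, half))
  expect_equal(out, x, tolerance = 1e-10)

  # pure 5 Hz sine against a zero reference: fully cancelled
  s5 <- sine(5, fs, n)
  out5 <- spectral_cancel(s5, fs, c(0, 20), reference = rep(0, half))
  expect_lt(sqrt(mean(out5^2)), 1e-6 * sqrt(mean(s5^2)))

  # white noise: out-of-band bins untouched, in-band bins <= reference
  set.seed(16)
  w <- rnorm(n)
  ref <- rep(0.01, half)
  ow <- spectral_cancel(w, fs, c(0, 20), reference = ref)
  spw <- amplitude_spectrum(w, fs); spo <- amplitude_spectrum(ow, fs)
  out_band <- spw$freq > 20
  expect_equal(spo$amplitude[out_band], spw$amplitude[out_band],
               tolerance = 1e-10)
  in_band <- spw$freq > 0 & spw$freq <= 20
  expect_true(all(spo$amplitude[in_band] <= ref[in_band] * (1 + 1e-8)))

  expect_error(spectral_cancel(w, fs, c(0, 600), rep(0, half)), "fs/2")
  expect_error(spectral_cancel(w, fs, c(0, 20), rep(0, 5)), "one value per")
})

test_that("invalid channels are rebuilt from grid neighbours", {
  g <- electrode_grid(3, 3, NULL)
  n <- 20
  # linear spatial gradient: value = 2*row + 3*col
  vals <- 2 * g$coord[, "row"] + 3 * g$coord[, "col"]
  x <- matrix(rep(vals, n), ncol = n)
  rec <- rec_of(x, grid = g)
  centre <- g$index[2, 2]
  rec$valid_mask[centre] <- FALSE
  rec$data[centre, ] <- 999
  fixed <- interpolate_channels(rec)
  expect_equal(fixed$data[centre, ], rep(vals[centre], n))
  expect_true(all(fixed$valid_mask))

  # corner channel: mean of its 2 available neighbours
  rec2 <- rec_of(x, grid = g)
  corner <- g$index[1, 1]
  rec2$valid_mask[corner] <- FALSE
  fixed2 <- interpolate_channels(rec2)
  expect_equal(fixed2$data[corner, 1],
               mean(c(vals[g$index[2, 1]], vals[g$index[1, 2]])))

  # untouched when nothing is invalid
  rec3 <- rec_of(x, grid = g)
  expect_identical(interpolate_channels(rec3)$data, rec3$data)

  # all neighbours invalid is an error
  rec4 <- rec_of(x, grid = g)
  rec4$valid_mask[c(g$index[2, 2], g$index[1, 2], g$index[3, 2],
                    g$index[2, 1], g$index[2, 3])] <- FALSE
  expect_error(interpolate_channels(rec4), "no valid neighbour")
})

test_that("component cleaning removes low-frequency artifact and keeps EMG", {
  st <- small_sim(seed = 21)
  ds <- emg_downsample(st$observed, 1000)
  cl <- clean_components(ds, "cca")
  expect_gt(length(cl$flag_report$flagged), 0)

  # fidelity: cleaned vs ground-truth clean in the myoelectric band
  cm <- emg_downsample(st$clean, 1000)
  a <- emg_bandpass(cl$recording, 101, 499)$data
  b <- emg_bandpass(cm, 101, 499)$data
  expect_gt(cor(as.vector(a), as.vector(b)), 0.95)

  # 0-20 Hz content drops substantially relative to the contaminated input
  raw020 <- mean(sapply(seq_len(64), function(i)
    band_amp_sum(ds$data[i, ], 1000, 0, 20)))
  cln020 <- mean(sapply(seq_len(64), function(i)
    band_amp_sum(cl$recording$data[i, ], 1000, 0, 20)))
  expect_lt(cln020, 0.2 * raw020)
})
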