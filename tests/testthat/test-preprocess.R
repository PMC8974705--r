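test_that("downsampling preserves in-band content and suppresses aliases", {
  fs <- 2048; n <- fs * 4
  g <- NULL

  # DC passes unchanged
  dc <- emg_downsample(rec_of(matrix(3.5, 2, n), fs = fs), 1000)
  expect_equal(dc$fs, 1000)
  expect_equal(ncol(dc$data), floor(n * 1000 / 2048))
  expect_equal(max(abs(dc$data - 3.5)), 0, tolerance = 1e-6)

  # 100 Hz sine: FFT peak at 100 Hz, amplitude within 2 %
  y <- emg_downsample(rec_of(matrix(sine(100, fs, n), 1), fs = fs), 1000)
  sp <- amplitude_spectrum(y$data[1, ], 1000)
  expect_equal(sp$freq[which.max(sp$amplitude)], 100)
  expect_equal(max(sp$amplitude), 1, tolerance = 0.02)

  # 600 Hz sine is above the new Nyquist: residual < 1 % of input
  y6 <- emg_downsample(rec_of(matrix(sine(600, fs, n), 1), fs = fs), 1000)
  expect_lt(sine_amp(y6$data[1, ]), 0.01)

  expect_error(emg_downsample(dc, 2000), "below")
})

test_that("zero-phase band-pass and high-pass match closed-form gains", {
  fs <- 1000; n <- 10000

  # high-pass, 4th order, 20 Hz
  hp200 <- emg_highpass(rec_of(matrix(sine(200, fs, n), 1), fs = fs))
  g_true <- butter_gain2(200, 20, 4, "high", fs = fs)
  expect_equal(sine_amp(hp200$data[1, ]), g_true, tolerance = 0.01)

  hp5 <- emg_highpass(rec_of(matrix(sine(5, fs, n), 1), fs = fs))
  g5 <- butter_gain2(5, 20, 4, "high", fs = fs)
  expect_lt(sine_amp(hp5$data[1, ]), g5 * 1.02 + 1e-6)

  # DC rejection
  hpdc <- emg_highpass(rec_of(matrix(7, 1, n), fs = fs))
  expect_lt(max(abs(hpdc$data)), 1e-8)

  # band-pass 10-500 at 2048 Hz
  fs2 <- 2048; n2 <- 20000
  bp100 <- emg_bandpass(rec_of(matrix(sine(100, fs2, n2), 1), fs = fs2), 10, 500)
  gb <- butter_gain2(100, c(10, 500), 4, "pass", fs = fs2)
  expect_equal(sine_amp(bp100$data[1, ]), gb, tolerance = 0.02)
  expect_gt(sine_amp(bp100$data[1, ]), 0.98)

  bp1 <- emg_bandpass(rec_of(matrix(sine(1, fs2, n2), 1), fs = fs2), 10, 500)
  expect_lt(sine_amp(bp1$data[1, ]),
            butter_gain2(1, c(10, 500), 4, "pass", fs = fs2) * 1.05)

  z <- emg_bandpass(rec_of(matrix(0, 1, n2), fs = fs2), 10, 500)
  expect_equal(max(abs(z$data)), 0)

  expect_error(emg_bandpass(bp1, 500, 10), "low < high")
  expect_error(emg_highpass(bp1, cutoff = 2000), "fs/2")
})

test_that("filters are linear and zero-phase", {
  fs <- 1000; n <- 6000
  set.seed(11)
  a <- rnorm(n); b <- rnorm(n)
  fa <- emg_highpass(rec_of(matrix(a, 1), fs = fs))$data[1, ]
  fb <- emg_highpass(rec_of(matrix(b, 1), fs = fs))$data[1, ]
  fab <- emg_highpass(rec_of(matrix(3 * a - 2 * b, 1), fs = fs))$data[1, ]
  expect_equal(fab, 3 * fa - 2 * fb, tolerance = 1e-9)

  # zero-phase: cross-correlation peak between input and output at lag 0
  cc <- ccf(a, fa, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("iterative z-score screening matches an independent implementation", {
  set.seed(3)
  for (rep in 1:5) {
    x <- matrix(rnorm(64 * 1500), 64)
    rec <- rec_of(x)
    rpt <- screen_channels(rec)
    expect_identical(rpt$rejected, screen_brute(x))
  }

  # null data: false rejections are rare under the z = 3 rule
  set.seed(4)
  n_rej <- replicate(20, {
    x <- matrix(rnorm(64 * 1500), 64)
    length(screen_channels(rec_of(x))$rejected)
  })
  expect_lt(mean(n_rej), 2)

  # a single grossly scaled channel is the one rejected
  x <- matrix(rnorm(64 * 1500), 64)
  x[17, ] <- x[17, ] * 100
  expect_identical(screen_channels(rec_of(x))$rejected, 17L)

  # identical channels: zero dispersion, nothing rejected
  same <- rec_of(matrix(rep(sine(50, 1000, 1000), each = 64), 64))
  expect_length(screen_channels(same)$rejected, 0L)

  # permutation equivariance
  set.seed(5)
  x <- matrix(rnorm(32 * 1200), 32)
  x[c(4, 20), ] <- x[c(4, 20), ] * 30
  perm <- sample(32)
  r1 <- screen_channels(rec_of(x))$rejected
  r2 <- screen_channels(rec_of(x[perm, ]))$rejected
  expect_setequal(match(r1, perm), r2)

  expect_error(screen_channels(rec_of(matrix(rnorm(4 * 100), 4))), "at least 8")
})

test_that("scaled-MAD spectral outlier exclusion", {
  set.seed(6)
  sp <- matrix(abs(rnorm(40 * 100, mean = 5)), 40)
  expect_identical(exclude_spectral_outliers(sp), 1:40)

  sp[13, ] <- sp[13, ] * 1000
  kept <- exclude_spectral_outliers(sp)
  expect_false(13 %in% kept)
  expect_length(kept, 39)
  # its deviation really is beyond 10 scaled MADs (direct computation)
  summ <- rowMeans(sp)
  expect_gt(abs(summ[13] - median(summ)) / mad(summ), 10)

  # identical spectra: zero MAD, all kept
  same <- matrix(1, 10, 50)
  expect_identical(exclude_spectral_outliers(same), 1:10)

  # two channels: degenerate, both kept
  expect_identical(exclude_spectral_outliers(sp[1:2, ]), 1:2)
})
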