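test_that("RMS maps normalize to the peak location", {
  # channels with amplitudes 1, 2, 4 -> normalized 0.25, 0.5, 1
  n <- 1000
  s <- sine(80, 1000, n)
  rec <- rec_of(rbind(1 * s, 2 * s, 4 * s))
  m <- rms_map(list(rec))
  expect_equal(m$values, c(0.25, 0.5, 1))
  # a unit sine has RMS 1/sqrt(2) before normalization
  expect_equal(m$rms_uv[1], 1 / sqrt(2), tolerance = 1e-3)

  # equal amplitudes -> all ones
  eq <- rms_map(rec_of(rbind(s, -s, s)))
  expect_equal(eq$values, c(1, 1, 1))

  # pooling across windows weights samples, not windows
  w1 <- rec_of(matrix(2, 2, 100)); w2 <- rec_of(matrix(0, 2, 300))
  pooled <- rms_map(list(w1, w2))
  expect_equal(pooled$rms_uv, rep(sqrt(4 * 100 / 400), 2))

  # invalid channels are excluded from the peak and set NA
  rec$valid_mask[3] <- FALSE
  m2 <- rms_map(list(rec))
  expect_true(is.na(m2$values[3]))
  expect_equal(m2$values[1:2], c(0.5, 1))
})

test_that("bilinear map interpolation preserves nodes and range", {
  m <- matrix(c(0, 0, 0, 1), 2, 2)
  dense <- interpolate_map(m, factor = 2)
  expect_equal(dim(dense), c(3L, 3L))
  expect_equal(dense[2, 2], 0.25)        # hand-computed bilinear centre
  expect_equal(dense[c(1, 3), c(1, 3)], m)

  # constant map stays constant; factor 1 is the identity
  expect_equal(interpolate_map(matrix(5, 3, 4), 3),
               matrix(5, 7, 10))
  expect_identical(interpolate_map(m, 1), m)

  # output bounded by input range
  set.seed(20)
  r <- matrix(runif(12), 3, 4)
  d8 <- interpolate_map(r, 8)
  expect_gte(min(d8), min(r) - 1e-12)
  expect_lte(max(d8), max(r) + 1e-12)

  # NA corner filled from neighbours before refining
  rn <- r; rn[1, 1] <- NA
  expect_false(anyNA(interpolate_map(rn, 2)))

  # full 13x5 map from a spatial_map object
  g <- electrode_grid()
  rec <- rec_of(matrix(rnorm(59 * 500), 59), montage = "differential", grid = g)
  sm <- rms_map(list(rec))
  dd <- interpolate_map(sm, 8)
  expect_equal(dim(dd), c(11 * 8 + 1, 4 * 8 + 1))
})

test_that("band decrease percentages behave as contracted", {
  set.seed(21)
  g <- electrode_grid()
  raw <- rec_of(matrix(rnorm(59 * 4000), 59), montage = "differential", grid = g)

  same <- band_decrease(raw, raw)
  expect_equal(same$pct_decrease, rep(0, 4))

  zero <- raw; zero$data[] <- 0
  gone <- band_decrease(raw, zero)
  expect_equal(gone$pct_decrease, rep(100, 4))

  # scale invariance
  half <- raw; half$data <- raw$data * 0.5
  d1 <- band_decrease(raw, half)
  raw2 <- raw; raw2$data <- raw$data * 7
  half2 <- raw; half2$data <- half$data * 7
  expect_equal(band_decrease(raw2, half2)$pct_decrease, d1$pct_decrease,
               tolerance = 1e-10)
  expect_equal(d1$pct_decrease, rep(50, 4), tolerance = 1e-8)

  # high-passed white noise: 0-20 band drops far more than 101-500,
  # which stays within the Butterworth passband bound
  hp <- emg_highpass(raw, 20)
  d <- band_decrease(raw, hp)
  expect_gt(d$pct_decrease[1], 80)
  worst_gain <- butter_gain2(101, 20, 4, "high", fs = 1000)
  expect_lt(d$pct_decrease[4], 100 * (1 - worst_gain) + 1)
  # tiny negative values can arise from finite-length edge effects
  expect_gt(min(d$pct_decrease), -1)

  expect_error(band_decrease(raw, rec_of(matrix(0, 59, 10),
                                         montage = "differential", grid = g)),
               "shape")
})

test_that("BH adjustment agrees exactly with the brute-force step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.3), 0.3)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(22)
  for (i in 1:1000) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(c(1, 3), 1)
    expect_equal(fdr_adjust(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("repeated-measures ANOVA matches hand computation and aov()", {
  # 3 subjects x 3 methods toy table, worked by hand:
  # y = [10 12 14; 11 15 16; 9 10 14]
  y <- matrix(c(10, 11, 9, 12, 15, 10, 14, 16, 14), 3, 3)
  arr <- array(y, c(3, 3, 1))
  out <- location_anova(arr)
  gm <- mean(y)
  ss_meth <- 3 * sum((colMeans(y) - gm)^2)
  ss_subj <- 3 * sum((rowMeans(y) - gm)^2)
  ss_err <- sum((y - gm)^2) - ss_meth - ss_subj
  f_hand <- (ss_meth / 2) / (ss_err / 4)
  expect_equal(out$F, f_hand)
  expect_equal(out$p, pf(f_hand, 2, 4, lower.tail = FALSE))

  # independent route: stats::aov with an error stratum
  df <- data.frame(y = as.vector(y),
                   subject = factor(rep(1:3, 3)),
                   method = factor(rep(1:3, each = 3)))
  av <- summary(stats::aov(y ~ method + Error(subject), data = df))
  f_aov <- av[["Error: Within"]][[1]]["method", "F value"]
  expect_equal(out$F, f_aov, tolerance = 1e-10)

  # no method effect: F undefined, nothing significant
  same <- array(rep(c(5, 6, 7), 3), c(3, 3, 1))
  out0 <- location_anova(same)
  expect_false(out0$significant)

  # a planted offset at one location is detected after FDR
  set.seed(23)
  L <- 30
  arr2 <- array(rnorm(8 * 3 * L, sd = 0.05), c(8, 3, L))
  arr2[, 2, 7] <- arr2[, 2, 7] + 1
  out2 <- location_anova(arr2)
  expect_true(out2$significant[7])
  expect_lte(sum(out2$significant[-7]), 2)

  # incomplete blocks are skipped
  arr3 <- arr2
  arr3[1, 1, 3] <- NA
  expect_message(out3 <- location_anova(arr3), "skipped 1")
  expect_true(is.na(out3$F[3]))
})

test_that("null method effects stay within the FDR significance budget", {
  set.seed(24)
  frac <- replicate(60, {
    arr <- array(rnorm(8 * 3 * 59), c(8, 3, 59))
    mean(location_anova(arr)$significant)
  })
  mc_err <- sd(frac) / sqrt(length(frac))
  expect_lte(mean(frac), 0.05 + 3 * mc_err)
})
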