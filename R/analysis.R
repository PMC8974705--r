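#' Spatial RMS activation map over gait-phase windows
#'
#' Pools all supplied windows' samples per channel, takes the root mean
#' square, and normalizes by the maximum RMS over valid channels, giving
#' per-electrode-location values in `[0, 1]` with the peak location at 1.
#'
#' @param windows A list of [emg_recording()] windows (e.g. from
#'   [extract_phase()]) with a consistent channel count, or a single
#'   recording.
#' @return An object of class `spatial_map`: `values` (normalized RMS per
#'   channel, `NA` for invalid channels), `rms_uv` (unnormalized RMS),
#'   `normalization` (peak RMS in microvolts), `montage`, `grid`,
#'   `valid_mask`.
#' @export
rms_map <- function(windows) {
  if (inherits(windows, "emg_recording")) windows <- list(windows)
  if (!length(windows)) stop("rms_map: need at least one window")
  nch <- nrow(windows[[1]]$data)
  if (!all(vapply(windows, function(w) nrow(w$data), 0L) == nch))
    stop("rms_map: inconsistent channel counts across windows")
  ss <- rep(0, nch); n <- 0L
  for (w in windows) {
    ss <- ss + rowSums(w$data^2)
    n <- n + ncol(w$data)
  }
  rms <- unname(sqrt(ss / n))
  vm <- unname(windows[[1]]$valid_mask)
  if (!any(vm)) stop("rms_map: no valid channels")
  peak <- max(rms[vm])
  if (peak <= 0) stop("rms_map: all-zero valid channels")
  vals <- rms / peak
  vals[!vm] <- NA_real_
  structure(list(values = vals, rms_uv = rms, normalization = peak,
                 montage = windows[[1]]$montage, grid = windows[[1]]$grid,
                 valid_mask = vm), class = "spatial_map")
}

#' @export
print.spatial_map <- function(x, ...) {
  cat(sprintf("<spatial_map> %d %s locations, peak RMS %.3g uV\n",
              length(x$values), x$montage, x$normalization))
  invisible(x)
}

#' Arrange a spatial map on its grid layout
#'
#' Returns the map as a rows x cols matrix. Monopolar maps use the
#' electrode layout; differential maps use the inter-electrode layout
#' (one row fewer), each value at the proximal row of its pair. Positions
#' without a channel are `NA`.
#'
#' @param map A `spatial_map`.
#' @return Numeric matrix.
#' @export
map_matrix <- function(map) {
  stopifnot(inherits(map, "spatial_map"))
  g <- map$grid
  if (is.null(g)) stop("map_matrix: map has no grid")
  if (map$montage == "monopolar") {
    out <- matrix(NA_real_, g$n_rows, g$n_cols)
    out[g$coord] <- map$values
  } else {
    pairs <- differential_pairs(g)
    out <- matrix(NA_real_, g$n_rows - 1L, g$n_cols)
    out[pairs[, c("row", "col")]] <- map$values
  }
  out
}

#' Bilinear interpolation of a spatial map
#'
#' Refines the map layout by `factor` per axis with bilinear interpolation
#' (output size `(R-1)*factor + 1` by `(C-1)*factor + 1`), as used to
#' render spatial activation maps. Original node values are preserved and
#' interpolated values stay within the input range. `NA` positions (the
#' missing corner, invalid channels) are first filled with the mean of
#' their available 4-neighbours so the interpolation is defined
#' everywhere.
#'
#' @param map A `spatial_map` or a numeric layout matrix.
#' @param factor Integer refinement factor >= 1. Default 8.
#' @return A dense numeric matrix.
#' @export
interpolate_map <- function(map, factor = 8L) {
  m <- if (inherits(map, "spatial_map")) map_matrix(map) else as.matrix(map)
  factor <- as.integer(factor)
  if (factor < 1L) stop("interpolate_map: factor must be >= 1")
  # fill NA nodes from available neighbours (repeat for chained NAs)
  for (pass in seq_len(nrow(m) + ncol(m))) {
    nas <- which(is.na(m), arr.ind = TRUE)
    if (!nrow(nas)) break
    for (k in seq_len(nrow(nas))) {
      r <- nas[k, 1]; c <- nas[k, 2]
      nb <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
      nb <- nb[nb[, 1] >= 1 & nb[, 1] <= nrow(m) &
               nb[, 2] >= 1 & nb[, 2] <= ncol(m), , drop = FALSE]
      v <- m[nb]
      if (any(!is.na(v))) m[r, c] <- mean(v, na.rm = TRUE)
    }
  }
  if (factor == 1L) return(m)
  R <- nrow(m); C <- ncol(m)
  ro <- seq(1, R, length.out = (R - 1L) * factor + 1L)
  co <- seq(1, C, length.out = (C - 1L) * factor + 1L)
  out <- matrix(0, length(ro), length(co))
  for (i in seq_along(ro)) {
    r0 <- min(floor(ro[i]), R - 1L); fr <- ro[i] - r0
    for (j in seq_along(co)) {
      c0 <- min(floor(co[j]), C - 1L); fc <- co[j] - c0
      out[i, j] <- (1 - fr) * (1 - fc) * m[r0, c0] +
                   (1 - fr) * fc * m[r0, c0 + 1] +
                   fr * (1 - fc) * m[r0 + 1, c0] +
                   fr * fc * m[r0 + 1, c0 + 1]
    }
  }
  out
}

#' Default analysis frequency bands
#'
#' The four bands used for band-wise spectral comparison, with the
#' half-open convention `(low, high]`: 0-20 Hz (motion artifact), 21-50 Hz
#' (artifact and low EMG overlap), 51-100 Hz, 101-500 Hz (myoelectric
#' signal).
#'
#' @return A 4 x 2 matrix of band edges in Hz.
#' @export
default_bands <- function() {
  rbind(c(0, 20), c(20, 50), c(50, 100), c(100, 500))
}

band_label <- function(bands)
  sprintf("%d-%d Hz", ifelse(bands[, 1] == 0, 0, bands[, 1] + 1), bands[, 2])

#' Band-wise spectral amplitude decrease versus raw data
#'
#' For each channel, computes one-sided FFT amplitude spectra of the raw
#' and the processed recording, sums the amplitudes inside each band
#' `(low, high]`, and reports the percent decrease
#' `100 (sum_raw - sum_processed) / sum_raw`. Percentages are averaged
#' over the channels kept by [exclude_spectral_outliers()] applied to the
#' raw spectra (default > 10 scaled MADs excluded), and the standard error
#' over channels is reported. A band with zero raw amplitude is
#' undefined (`NA`).
#'
#' @param raw,processed [emg_recording()]s of identical shape and rate.
#' @param bands Band-edge matrix; default [default_bands()].
#' @param mad_thresh Outlier threshold passed to
#'   [exclude_spectral_outliers()].
#' @return A data frame of class `band_report`: `band`, `low`, `high`,
#'   `pct_decrease`, `se`, `n_channels`.
#' @export
band_decrease <- function(raw, processed, bands = default_bands(),
                          mad_thresh = 10) {
  stopifnot(inherits(raw, "emg_recording"), inherits(processed, "emg_recording"))
  if (!all(dim(raw$data) == dim(processed$data)) || raw$fs != processed$fs)
    stop("band_decrease: raw and processed must share shape and rate")
  valid <- which(raw$valid_mask & processed$valid_mask)
  sp_raw <- do.call(rbind, lapply(valid, function(i)
    amplitude_spectrum(raw$data[i, ], raw$fs)$amplitude))
  sp_pro <- do.call(rbind, lapply(valid, function(i)
    amplitude_spectrum(processed$data[i, ], raw$fs)$amplitude))
  freq <- amplitude_spectrum(raw$data[valid[1], ], raw$fs)$freq
  keep <- exclude_spectral_outliers(sp_raw, mad_thresh = mad_thresh)
  sp_raw <- sp_raw[keep, , drop = FALSE]
  sp_pro <- sp_pro[keep, , drop = FALSE]
  out <- lapply(seq_len(nrow(bands)), function(b) {
    sel <- freq > bands[b, 1] & freq <= bands[b, 2]
    s_raw <- rowSums(sp_raw[, sel, drop = FALSE])
    s_pro <- rowSums(sp_pro[, sel, drop = FALSE])
    ok <- s_raw > 0
    pct <- 100 * (s_raw[ok] - s_pro[ok]) / s_raw[ok]
    data.frame(band = band_label(bands)[b],
               low = bands[b, 1], high = bands[b, 2],
               pct_decrease = if (any(ok)) mean(pct) else NA_real_,
               se = if (sum(ok) > 1) stats::sd(pct) / sqrt(sum(ok)) else NA_real_,
               n_channels = sum(ok))
  })
  structure(do.call(rbind, out), class = c("band_report", "data.frame"))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR-adjusted p-values (`min` over the step-up path of
#' `p_(i) m / i`, clipped at 1), monotone in rank. Delegates to
#' [stats::p.adjust()] with `method = "BH"`; `NA`s are preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("fdr_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-location one-way repeated-measures ANOVA with FDR correction
#'
#' Compares processing methods at each electrode location: a one-way
#' repeated-measures ANOVA with subject as the blocking factor,
#' `F = MS_method / MS_error` with `(k - 1)` and `(n - 1)(k - 1)` degrees
#' of freedom, computed per location from the complete subject x method
#' block. P-values are FDR-adjusted across locations
#' ([fdr_adjust()]) and flagged significant at `alpha`. Locations with
#' incomplete blocks (any `NA`) are skipped with a message. When both the
#' method and error sums of squares vanish (all methods identical within
#' subject), F is undefined and the location is non-significant.
#'
#' @param rms_values 3-d array `[subjects, methods, locations]` of (RMS)
#'   values.
#' @param alpha Significance level after adjustment. Default 0.05.
#' @return A data frame of class `location_stats`: `location`, `F`, `df1`,
#'   `df2`, `p`, `p_adj`, `significant`.
#' @export
location_anova <- function(rms_values, alpha = 0.05) {
  d <- dim(rms_values)
  if (length(d) != 3L) stop("location_anova: need subjects x methods x locations array")
  n <- d[1]; k <- d[2]; L <- d[3]
  if (k < 2L) stop("location_anova: need at least 2 methods")
  if (n < 3L) stop("location_anova: need at least 3 subjects")
  Fv <- p <- rep(NA_real_, L)
  skipped <- 0L
  for (l in seq_len(L)) {
    y <- rms_values[, , l]
    if (anyNA(y)) { skipped <- skipped + 1L; next }
    gm <- mean(y)
    ss_subj <- k * sum((rowMeans(y) - gm)^2)
    ss_meth <- n * sum((colMeans(y) - gm)^2)
    ss_tot <- sum((y - gm)^2)
    ss_err <- ss_tot - ss_subj - ss_meth
    df1 <- k - 1; df2 <- (n - 1) * (k - 1)
    ms_err <- ss_err / df2
    if (ms_err <= .Machine$double.eps * max(1, ss_tot)) {
      if (ss_meth <= .Machine$double.eps * max(1, ss_tot)) {
        Fv[l] <- NA_real_; p[l] <- 1
      } else {
        Fv[l] <- Inf; p[l] <- 0
      }
    } else {
      Fv[l] <- (ss_meth / df1) / ms_err
      p[l] <- stats::pf(Fv[l], df1, df2, lower.tail = FALSE)
    }
  }
  if (skipped) message("location_anova: skipped ", skipped,
                       " location(s) with incomplete blocks")
  p_adj <- fdr_adjust(p)
  structure(data.frame(
    location = seq_len(L), F = Fv, df1 = k - 1, df2 = (n - 1) * (k - 1),
    p = p, p_adj = p_adj,
    significant = !is.na(p_adj) & p_adj < alpha
  ), class = c("location_stats", "data.frame"), alpha = alpha)
}
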