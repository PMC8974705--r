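#' PCA decomposition of a multichannel EMG recording
#'
#' Removes each channel's mean and eigendecomposes the channel covariance.
#' Components (sources) are the projections of the centered data on the
#' eigenvectors, ordered by descending eigenvalue; scores are the variance
#' fractions. Only channels flagged valid in the recording enter the
#' decomposition. Non-positive eigenvalues of rank-deficient inputs are
#' dropped with a message.
#'
#' @param rec An [emg_recording()] with more samples than valid channels.
#' @return An object of class `component_set`: `sources` (components x
#'   samples), `mixing` (channels x components), `unmixing` (components x
#'   channels), `center` (channel means), `scores`, `method`, `channels`
#'   (indices of the recording channels decomposed), `fs`, `lag` (CCA
#'   only) and `flags` (all `FALSE` until [flag_components()]).
#' @export
pca_decompose <- function(rec) {
  stopifnot(inherits(rec, "emg_recording"))
  x <- rec$data[rec$valid_mask, , drop = FALSE]
  if (nrow(x) < 2L) stop("pca_decompose: need at least 2 valid channels")
  if (ncol(x) <= nrow(x)) stop("pca_decompose: need more samples than channels")
  ctr <- rowMeans(x)
  xc <- x - ctr
  cv <- tcrossprod(xc) / (ncol(xc) - 1)
  e <- eigen(cv, symmetric = TRUE)
  tol <- max(e$values) * 1e-12
  keep <- e$values > tol
  if (!all(keep))
    message("pca_decompose: input rank-deficient; retaining ",
            sum(keep), " of ", length(keep), " components")
  V <- e$vectors[, keep, drop = FALSE]
  lam <- e$values[keep]
  structure(list(
    sources = crossprod(V, xc),
    mixing = V,
    unmixing = t(V),
    center = ctr,
    scores = lam / sum(lam),
    eigenvalues = lam,
    method = "pca",
    channels = which(rec$valid_mask),
    fs = rec$fs,
    lag = NULL,
    flags = rep(FALSE, sum(keep))
  ), class = "component_set")
}

#' CCA decomposition by lag-1 autocorrelation
#'
#' Blind source separation via canonical correlation analysis between the
#' multichannel signal and its time-lagged copy. With `X_a = X(t)` and
#' `X_b = X(t - lag)` the canonical directions solve the symmetric
#' generalized eigenproblem
#' `C_s w = rho C_0 w`, where `C_s` is the symmetrized lagged covariance
#' `(X_a X_b' + X_b X_a') / 2` and `C_0` the average zero-lag covariance.
#' Each eigenvalue is the corresponding component's lag-`lag`
#' autocorrelation, so components are ordered from slow (high
#' autocorrelation, artifact-like) to fast. The stored scores are the
#' empirical lag-`lag` Pearson autocorrelations of the component time
#' series. A small ridge (`1e-9 x mean channel variance`) stabilizes the
#' whitening for near-singular covariances.
#'
#' @param rec An [emg_recording()].
#' @param lag Lag in samples. Default 1.
#' @return A `component_set`; see [pca_decompose()].
#' @export
cca_decompose <- function(rec, lag = 1L) {
  stopifnot(inherits(rec, "emg_recording"))
  lag <- as.integer(lag)
  x <- rec$data[rec$valid_mask, , drop = FALSE]
  nch <- nrow(x); n <- ncol(x)
  if (nch < 2L) stop("cca_decompose: need at least 2 valid channels")
  if (n <= nch + lag) stop("cca_decompose: need more samples than channels + lag")
  ctr <- rowMeans(x)
  xc <- x - ctr
  a <- xc[, seq_len(n - lag), drop = FALSE]
  b <- xc[, (1L + lag):n, drop = FALSE]
  m <- n - lag
  c0 <- (tcrossprod(a) + tcrossprod(b)) / (2 * (m - 1))
  cs <- (tcrossprod(a, b) + tcrossprod(b, a)) / (2 * (m - 1))
  ridge <- 1e-9 * mean(diag(c0))
  c0 <- c0 + diag(ridge, nch)
  e0 <- eigen(c0, symmetric = TRUE)
  if (min(e0$values) < 1e-10 * max(e0$values))
    message("cca_decompose: ill-conditioned covariance; ridge-regularized whitening")
  w_half <- e0$vectors %*% (t(e0$vectors) / sqrt(e0$values))   # C0^{-1/2}
  m_sym <- w_half %*% cs %*% w_half
  m_sym <- (m_sym + t(m_sym)) / 2
  eu <- eigen(m_sym, symmetric = TRUE)
  unmix <- t(w_half %*% eu$vectors)          # rows: components
  mix <- e0$vectors %*% (t(e0$vectors) * sqrt(e0$values)) %*% eu$vectors
  # normalize mixing columns to unit norm so each component time series
  # carries its channel-space magnitude (as PCA's orthonormal basis does);
  # cross-component spectral comparisons are then scale-consistent
  nrm <- sqrt(colSums(mix^2))
  mix <- sweep(mix, 2L, nrm, "/")
  unmix <- unmix * nrm
  sources <- unmix %*% xc
  acorr <- vapply(seq_len(nrow(sources)), function(i) {
    s <- sources[i, ]
    stats::cor(s[seq_len(n - lag)], s[(1L + lag):n])
  }, 0)
  ord <- order(acorr, decreasing = TRUE)
  structure(list(
    sources = sources[ord, , drop = FALSE],
    mixing = mix[, ord, drop = FALSE],
    unmixing = unmix[ord, , drop = FALSE],
    center = ctr,
    scores = acorr[ord],
    eigenvalues = eu$values[ord],
    method = "cca",
    channels = which(rec$valid_mask),
    fs = rec$fs,
    lag = lag,
    flags = rep(FALSE, nch)
  ), class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("<component_set> %s: %d components x %d samples @ %g Hz, %d flagged\n",
              toupper(x$method), nrow(x$sources), ncol(x$sources), x$fs,
              sum(x$flags)))
  cat(sprintf("  top scores: %s\n",
              paste(signif(utils::head(x$scores, 5), 4), collapse = ", ")))
  invisible(x)
}

#' One-sided amplitude spectra of component time series
#'
#' @param cs A `component_set`.
#' @param fs Sampling rate; defaults to the rate stored in `cs`.
#' @return A list with `freq` (Hz) and `amplitude` (components x bins).
#' @export
component_spectra <- function(cs, fs = cs$fs) {
  stopifnot(inherits(cs, "component_set"))
  if (!nrow(cs$sources)) stop("component_spectra: empty component set")
  sp <- lapply(seq_len(nrow(cs$sources)),
               function(i) amplitude_spectrum(cs$sources[i, ], fs))
  list(freq = sp[[1]]$freq,
       amplitude = do.call(rbind, lapply(sp, `[[`, "amplitude")))
}

#' Flag artifact-dominated components
#'
#' For each component, the fraction of total one-sided spectral amplitude
#' falling inside the artifact band `(low, high]` is computed. Components
#' whose band fraction exceeds the cross-component mean by more than
#' `z_thresh` standard deviations are flagged as artifact (statistical
#' comparison among components), provided the fraction also exceeds the
#' absolute dominance floor `min_fraction`: motion-artifact components
#' carry the bulk of their amplitude in-band, and the floor prevents a
#' merely atypical myoelectric component from being edited, which would
#' inject rather than remove content on clean data. For CCA sets, any
#' component whose lag autocorrelation score exceeds `score_ceiling` is
#' additionally flagged: near-unit autocorrelation marks quasi-DC drift
#' the spectral statistic can miss. With fewer than 3 components the
#' comparison is degenerate and nothing is flagged.
#'
#' @param cs A `component_set`.
#' @param fs Sampling rate; defaults to `cs$fs`.
#' @param artifact_band `c(low, high)` in Hz. Default `c(0, 20)`.
#' @param z_thresh Threshold in standard deviations. Default 2.
#' @param min_fraction Absolute in-band fraction a component must exceed
#'   to be flagged. Default 0.2.
#' @param score_ceiling Autocorrelation ceiling for CCA flagging.
#'   Default 0.999.
#' @return A list of class `component_flag_report`: `band_fraction`,
#'   `threshold` (the mean + z x SD cut), `flagged` (indices), `z_thresh`,
#'   `artifact_band`, and the input `component_set` with `flags` set, in
#'   `$component_set`.
#' @export
flag_components <- function(cs, fs = cs$fs, artifact_band = c(0, 20),
                            z_thresh = 2, min_fraction = 0.2,
                            score_ceiling = 0.999) {
  stopifnot(inherits(cs, "component_set"))
  sp <- component_spectra(cs, fs)
  in_band <- sp$freq > artifact_band[1] & sp$freq <= artifact_band[2]
  tot <- rowSums(sp$amplitude)
  frac <- ifelse(tot > 0, rowSums(sp$amplitude[, in_band, drop = FALSE]) / tot, 0)
  k <- length(frac)
  flags <- rep(FALSE, k)
  thr <- NA_real_
  if (k >= 3L) {
    thr <- max(mean(frac) + z_thresh * stats::sd(frac), min_fraction)
    flags <- frac > thr
  }
  if (cs$method == "cca") flags <- flags | (cs$scores > score_ceiling)
  cs$flags <- flags
  structure(list(
    band_fraction = frac, threshold = thr, flagged = which(flags),
    z_thresh = z_thresh, artifact_band = artifact_band,
    score_ceiling = if (cs$method == "cca") score_ceiling else NA_real_,
    component_set = cs
  ), class = "component_flag_report")
}

#' @export
print.component_flag_report <- function(x, ...) {
  cat(sprintf("<component_flag_report> %d of %d component(s) flagged in (%g, %g] Hz\n",
              length(x$flagged), length(x$band_fraction),
              x$artifact_band[1], x$artifact_band[2]))
  invisible(x)
}

#' Spectral noise cancellation of one component
#'
#' Edits a component's FFT inside the artifact band: each in-band bin's
#' magnitude is reduced to the minimum of its own magnitude and the
#' reference magnitude at that bin, with phase preserved; out-of-band bins
#' are untouched. The reference is typically the cross-component median
#' amplitude per bin, so a flagged component is capped at what an
#' unremarkable component carries in that band. Inverse FFT returns the
#' real-valued cleaned component.
#'
#' @param source Numeric vector (one component's time series).
#' @param fs Sampling rate in Hz.
#' @param artifact_band `c(low, high)` in Hz.
#' @param reference Reference one-sided amplitude per bin (same length and
#'   scaling as [amplitude_spectrum()] of `source`).
#' @return The cleaned component, same length.
#' @export
spectral_cancel <- function(source, fs, artifact_band = c(0, 20), reference) {
  n <- length(source)
  if (artifact_band[1] < 0 || artifact_band[2] > fs / 2)
    stop("spectral_cancel: band must lie within (0, fs/2)")
  half <- floor(n / 2) + 1L
  if (length(reference) != half)
    stop("spectral_cancel: reference must have one value per one-sided bin")
  X <- stats::fft(source)
  freq <- (seq_len(half) - 1) * fs / n
  scale2 <- rep(2, half); scale2[1] <- 1
  if (n %% 2 == 0) scale2[half] <- 1
  amp <- Mod(X[seq_len(half)]) / n * scale2
  idx <- which(freq > artifact_band[1] & freq <= artifact_band[2] & amp > 0)
  for (i in idx) {
    if (amp[i] <= reference[i]) next
    g <- reference[i] / amp[i]
    X[i] <- X[i] * g
    j <- n - i + 2L               # conjugate-symmetric partner
    if (j >= 2L && j <= n && j != i) X[j] <- X[j] * g
  }
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Reconstruct channel data from (cleaned) components
#'
#' Maps component time series back to channel space: `mixing %*% sources`
#' plus the stored channel means. Channels that were not part of the
#' decomposition (screened out) are left untouched in the returned
#' recording and remain invalid.
#'
#' @param cs A `component_set`.
#' @param cleaned_sources Matrix with the same shape as `cs$sources`;
#'   defaults to the unaltered sources.
#' @param rec The recording the components came from; reconstructed
#'   channels are written into a copy of it.
#' @return An [emg_recording()].
#' @export
reconstruct <- function(cs, cleaned_sources = cs$sources, rec) {
  stopifnot(inherits(cs, "component_set"), inherits(rec, "emg_recording"))
  if (!all(dim(cleaned_sources) == dim(cs$sources)))
    stop("reconstruct: cleaned_sources shape must match cs$sources")
  xhat <- cs$mixing %*% cleaned_sources + cs$center
  out <- rec
  out$data[cs$channels, ] <- xhat
  out
}

#' Clean a recording by component decomposition and spectral cancellation
#'
#' One full component-cleaning pass: decompose ([pca_decompose()] or
#' [cca_decompose()]), flag artifact components ([flag_components()]),
#' apply [spectral_cancel()] to every flagged component using the
#' cross-component median amplitude per bin as reference, and
#' [reconstruct()].
#'
#' Flagging and cancellation use separate bands: components are flagged
#' by their 0-20 Hz amplitude fraction (where pure motion artifact
#' lives), while flagged components are cancelled over 0-50 Hz by
#' default, covering both frequency bands associated with motion
#' artifacts during locomotion (0-20 and 21-50 Hz).
#'
#' @param rec An [emg_recording()].
#' @param method `"pca"` or `"cca"`.
#' @param lag CCA lag in samples. Default 1.
#' @param artifact_band,z_thresh,min_fraction,score_ceiling Passed to
#'   [flag_components()].
#' @param cancel_band Band edited by [spectral_cancel()] on flagged
#'   components. Default `c(0, 50)` Hz.
#' @return A list: `recording` (cleaned), `flag_report`, `component_set`.
#' @export
clean_components <- function(rec, method = c("cca", "pca"), lag = 1L,
                             artifact_band = c(0, 20), z_thresh = 2,
                             min_fraction = 0.2, score_ceiling = 0.999,
                             cancel_band = c(0, 50)) {
  method <- match.arg(method)
  cs <- if (method == "pca") pca_decompose(rec) else cca_decompose(rec, lag = lag)
  rep_ <- flag_components(cs, artifact_band = artifact_band,
                          z_thresh = z_thresh, min_fraction = min_fraction,
                          score_ceiling = score_ceiling)
  cs <- rep_$component_set
  cleaned <- cs$sources
  if (any(cs$flags)) {
    # edit on an even-reflection extension (circularly continuous), then
    # crop: plain FFT-bin editing of a non-periodic component concentrates
    # wrap-around transients at the segment edges
    n <- ncol(cs$sources)
    ext <- function(v) c(v, rev(v))
    spe <- do.call(rbind, lapply(seq_len(nrow(cs$sources)), function(i)
      amplitude_spectrum(ext(cs$sources[i, ]), cs$fs)$amplitude))
    ref <- apply(spe, 2L, stats::median)
    for (i in which(cs$flags))
      cleaned[i, ] <- spectral_cancel(ext(cs$sources[i, ]), cs$fs,
                                      artifact_band = cancel_band,
                                      reference = ref)[seq_len(n)]
  }
  list(recording = reconstruct(cs, cleaned, rec),
       flag_report = rep_, component_set = cs)
}

#' Interpolate screened-out channels from grid neighbours
#'
#' Replaces each invalid monopolar channel by the sample-wise mean of its
#' valid 4-neighbours (up/down/left/right on the electrode grid). All
#' interpolations use pre-interpolation values, so the result does not
#' depend on channel order. The validity mask is set true afterwards.
#'
#' @param rec A monopolar [emg_recording()] with a grid.
#' @param grid The [electrode_grid()]; defaults to `rec$grid`.
#' @return The recording with invalid channels filled in.
#' @export
interpolate_channels <- function(rec, grid = rec$grid) {
  stopifnot(inherits(rec, "emg_recording"))
  if (rec$montage != "monopolar")
    stop("interpolate_channels: only monopolar recordings are interpolated")
  if (is.null(grid)) stop("interpolate_channels: no grid supplied")
  bad <- which(!rec$valid_mask)
  if (!length(bad)) return(rec)
  orig <- rec$data
  for (ch in bad) {
    rc <- grid$coord[ch, ]
    nb <- rbind(rc + c(-1L, 0L), rc + c(1L, 0L), rc + c(0L, -1L), rc + c(0L, 1L))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= grid$n_rows &
             nb[, 2] >= 1 & nb[, 2] <= grid$n_cols, , drop = FALSE]
    ni <- grid$index[nb]
    ni <- ni[!is.na(ni)]
    ni <- ni[rec$valid_mask[ni]]
    if (!length(ni))
      stop("interpolate_channels: channel ", ch, " has no valid neighbour")
    rec$data[ch, ] <- colMeans(orig[ni, , drop = FALSE])
  }
  rec$valid_mask[bad] <- TRUE
  rec
}
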