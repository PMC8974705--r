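#' Statistical channel screening
#'
#' Flags unusually noisy channels by iterative z-score rejection, the
#' objective criterion used for channel cleaning in high-density mobile
#' EEG work. At each iteration the log-RMS and excess kurtosis of every
#' currently valid channel are standardized against the mean and standard
#' deviation over valid channels; channels with `|z| > z_thresh` on either
#' statistic are rejected, and the loop repeats until a fixed point or
#' `max_iter`. A statistic with (near-)zero dispersion across channels
#' rejects nothing.
#'
#' @param rec An [emg_recording()].
#' @param z_thresh Rejection threshold in standard deviations. Default 3.
#' @param max_iter Maximum refinement iterations. Default 8.
#' @return A list of class `screening_report`: `rejected` (channel
#'   indices), `stats` (per-channel log-RMS and kurtosis), `z_thresh`,
#'   `iterations`, and the updated recording in `$recording` (valid_mask
#'   cleared for rejected channels).
#' @export
screen_channels <- function(rec, z_thresh = 3, max_iter = 8L) {
  stopifnot(inherits(rec, "emg_recording"))
  if (sum(rec$valid_mask) < 8L)
    stop("screen_channels: need at least 8 valid channels")
  x <- rec$data
  log_rms <- log(pmax(sqrt(rowMeans(x^2)), .Machine$double.xmin))
  kurt <- apply(x, 1L, function(v) {
    v <- v - mean(v)
    m2 <- mean(v^2)
    if (m2 <= 0) 0 else mean(v^4) / m2^2 - 3
  })
  valid <- rec$valid_mask
  it <- 0L
  repeat {
    it <- it + 1L
    zs <- function(s) {
      mu <- mean(s[valid]); sd0 <- stats::sd(s[valid])
      if (!is.finite(sd0) || sd0 < 1e-12) return(rep(0, length(s)))
      (s - mu) / sd0
    }
    bad <- valid & (abs(zs(log_rms)) > z_thresh | abs(zs(kurt)) > z_thresh)
    if (!any(bad) || it >= max_iter) break
    valid[bad] <- FALSE
  }
  rejected <- which(rec$valid_mask & !valid)
  if (length(rejected) > 0.5 * sum(rec$valid_mask))
    stop("screen_channels: more than half of the channels fail screening; data unusable")
  rec$valid_mask <- valid
  structure(list(
    rejected = rejected,
    stats = data.frame(channel = seq_len(nrow(x)),
                       log_rms = log_rms, kurtosis = kurt),
    z_thresh = z_thresh, iterations = it, recording = rec
  ), class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> %d channel(s) rejected (z > %g, %d iteration(s))\n",
              length(x$rejected), x$z_thresh, x$iterations))
  if (length(x$rejected)) cat("  rejected:", paste(x$rejected, collapse = ", "), "\n")
  invisible(x)
}

#' One-sided amplitude spectrum
#'
#' Single-taper FFT amplitude spectrum of a vector, normalized so a unit
#' sinusoid at a bin centre has amplitude 1: `2 |X_k| / n` for interior
#' bins, `|X_k| / n` at DC (and Nyquist when n is even).
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @return A list with `freq` (Hz) and `amplitude`.
#' @export
amplitude_spectrum <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  half <- floor(n / 2) + 1L
  amp <- Mod(X[seq_len(half)]) / n
  scale2 <- rep(2, half); scale2[1] <- 1
  if (n %% 2 == 0) scale2[half] <- 1
  list(freq = (seq_len(half) - 1) * fs / n, amplitude = amp * scale2)
}

#' Exclude spectral outlier channels by scaled MAD
#'
#' For cross-channel spectral averaging, channels whose summary spectral
#' amplitude (the mean of their amplitude spectrum) deviates from the
#' cross-channel median by more than `mad_thresh` scaled median absolute
#' deviations are excluded. The MAD is scaled by 1.4826 for consistency
#' with the standard deviation under normality. With fewer than three
#' channels, or zero MAD, all channels are kept.
#'
#' @param spectra Matrix of per-channel amplitude spectra (channels x bins)
#'   or a list of `amplitude_spectrum()` results.
#' @param mad_thresh Threshold in scaled MADs. Default 10.
#' @return Integer vector of kept channel indices.
#' @export
exclude_spectral_outliers <- function(spectra, mad_thresh = 10) {
  if (is.list(spectra) && !is.matrix(spectra))
    spectra <- do.call(rbind, lapply(spectra, `[[`, "amplitude"))
  if (nrow(spectra) < 3L) return(seq_len(nrow(spectra)))
  summ <- rowMeans(spectra)
  med <- stats::median(summ)
  smad <- stats::mad(summ)  # constant = 1.4826 (scaled MAD)
  if (!is.finite(smad) || smad < 1e-300) return(seq_len(nrow(spectra)))
  which(abs(summ - med) / smad <= mad_thresh)
}
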