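# Zero-phase IIR filtering with reflective padding.
#
# signal::filtfilt applies the filter forward and backward but without edge
# padding or initial-condition matching, which leaves large startup
# transients for low cutoff frequencies. Here the input is extended at both
# ends by odd (point-symmetric) reflection before the forward-backward pass
# and trimmed afterwards. The pad length is derived from the slowest filter
# pole so the startup transient has decayed below 1e-9 before the retained
# segment begins.
zero_phase <- function(bf, x) {
  n <- length(x)
  poles <- polyroot(rev(bf$a))
  mm <- max(Mod(poles))
  np <- if (mm >= 1) n - 1L else
    min(n - 1L, max(3L * (length(bf$a) - 1L), ceiling(log(1e-9) / log(mm))))
  if (np < 1L) stop("zero_phase: input too short for this filter")
  xp <- c(2 * x[1] - x[(np + 1L):2],
          x,
          2 * x[n] - x[(n - 1L):(n - np)])
  y <- as.numeric(signal::filter(bf, xp))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(np + 1L):(np + n)]
}

# Apply a filter function rowwise over a channels x samples matrix.
filter_rows <- function(data, fun) {
  out <- data
  for (i in seq_len(nrow(data))) out[i, ] <- fun(data[i, ])
  out
}

#' Zero-phase Butterworth filters for EMG recordings
#'
#' All three filters are 4th-order Butterworth designs by default, applied
#' forward and backward (zero lag), so the effective magnitude response is
#' the squared analogue magnitude `|H(f)|^2` and the phase response is
#' identically zero.
#'
#' @param rec An [emg_recording()].
#' @param low,high Band edges in Hz for `emg_bandpass`.
#' @param cutoff Cutoff frequency in Hz.
#' @param order Filter order of the underlying one-way design. Default 4.
#' @return A filtered `emg_recording` of identical shape.
#' @seealso [filter_grf()] for the ground-reaction-force filter.
#' @export
emg_highpass <- function(rec, cutoff = 20, order = 4) {
  stopifnot(inherits(rec, "emg_recording"))
  if (cutoff <= 0 || cutoff >= rec$fs / 2)
    stop("emg_highpass: cutoff must lie in (0, fs/2)")
  bf <- signal::butter(order, cutoff / (rec$fs / 2), type = "high")
  rec$data <- filter_rows(rec$data, function(x) zero_phase(bf, x))
  rec
}

#' @rdname emg_highpass
#' @export
emg_bandpass <- function(rec, low = 10, high = 500, order = 4) {
  stopifnot(inherits(rec, "emg_recording"))
  if (!(0 < low && low < high && high < rec$fs / 2))
    stop("emg_bandpass: need 0 < low < high < fs/2")
  # order-per-edge: butter(n, c(lo, hi), "pass") gives a 2n-order filter
  bf <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  rec$data <- filter_rows(rec$data, function(x) zero_phase(bf, x))
  rec
}

#' Downsample an EMG recording with anti-alias filtering
#'
#' Rate conversion for the native 2048 Hz recordings to the 1000 Hz force
#' plate rate. A steep zero-phase low-pass (10th-order Butterworth at 0.9 x
#' the target Nyquist, applied forward-backward) suppresses content above
#' the new Nyquist, after which the band-limited signal is evaluated at the
#' new sample times by cubic spline interpolation. Output length is
#' `floor(n * target_fs / fs)`.
#'
#' @param rec An [emg_recording()].
#' @param target_fs Target rate in Hz, strictly below `rec$fs`.
#' @return The resampled `emg_recording` at `target_fs`.
#' @export
emg_downsample <- function(rec, target_fs = 1000) {
  stopifnot(inherits(rec, "emg_recording"))
  if (target_fs >= rec$fs)
    stop("emg_downsample: target_fs must be below the current rate")
  n <- ncol(rec$data)
  n_out <- floor(n * target_fs / rec$fs)
  bf <- signal::butter(10, 0.9 * (target_fs / 2) / (rec$fs / 2))
  t_in <- (seq_len(n) - 1) / rec$fs
  t_out <- (seq_len(n_out) - 1) / target_fs
  out <- matrix(0, nrow(rec$data), n_out)
  for (i in seq_len(nrow(rec$data))) {
    xf <- zero_phase(bf, rec$data[i, ])
    out[i, ] <- stats::spline(t_in, xf, xout = t_out)$y
  }
  emg_recording(out, target_fs, rec$montage, grid = rec$grid,
                valid_mask = rec$valid_mask)
}

# Closed-form squared magnitude of a zero-phase (forward-backward)
# Butterworth filter; used by tests as the analytic gain oracle.
#' Analytic gain of the zero-phase Butterworth designs
#'
#' Returns the amplitude gain `|H(f)|^2` of an order-`order` Butterworth
#' low-, high- or band-pass applied forward and backward, from the analogue
#' prototype magnitude. Intended for checking the digital filters against
#' their design response.
#'
#' @param f Frequency in Hz.
#' @param cutoff Cutoff (scalar) or band edges `c(low, high)` in Hz.
#' @param order Design order.
#' @param type `"low"`, `"high"` or `"pass"`.
#' @param fs Sampling rate in Hz. When finite, frequencies are bilinear
#'   prewarped (`tan(pi f / fs)`), giving the exact response of the digital
#'   design; `Inf` gives the analogue prototype response.
#' @return Gain values in `[0, 1]`.
#' @export
butter_gain2 <- function(f, cutoff, order = 4, type = c("low", "high", "pass"),
                         fs = Inf) {
  type <- match.arg(type)
  if (is.finite(fs)) {
    f <- tan(pi * f / fs)
    cutoff <- tan(pi * cutoff / fs)
  }
  h2 <- switch(type,
    low  = 1 / (1 + (f / cutoff[1])^(2 * order)),
    high = 1 / (1 + (cutoff[1] / f)^(2 * order)),
    pass = {
      w0 <- sqrt(cutoff[1] * cutoff[2]); bw <- cutoff[2] - cutoff[1]
      x <- (f^2 - w0^2) / (f * bw)
      1 / (1 + x^(2 * order))
    })
  h2  # one-way power response == two-way (zero-phase) amplitude response
}
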