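#' Low-pass filter a ground reaction force trace
#'
#' 4th-order Butterworth low-pass at 40 Hz, applied forward and backward
#' (zero lag), matching standard treadmill gait-event extraction practice.
#'
#' @param grf A `grf_series` (see [read_grf()]) or numeric vector.
#' @param fs Sampling rate in Hz when `grf` is a bare vector. Must exceed
#'   twice the cutoff.
#' @param cutoff Cutoff in Hz. Default 40.
#' @param order Filter order. Default 4.
#' @return A `grf_series` of the same length.
#' @export
filter_grf <- function(grf, fs = 1000, cutoff = 40, order = 4) {
  if (inherits(grf, "grf_series")) { fs <- grf$fs; grf <- grf$force }
  if (fs <= 2 * cutoff) stop("filter_grf: fs must exceed twice the cutoff")
  bf <- signal::butter(order, cutoff / (fs / 2))
  np_min <- 3L * order + 1L
  if (length(grf) <= np_min)
    stop("filter_grf: series shorter than the filter warm-up")
  structure(list(force = zero_phase(bf, grf), fs = fs), class = "grf_series")
}

#' Detect gait events from vertical ground reaction force
#'
#' Heel strikes are upward crossings of the force threshold and toe-offs
#' downward crossings. Crossings closer than `min_phase` to the previous
#' accepted event are discarded (debouncing). Only complete strides —
#' heel strike, toe-off, next heel strike — are retained, so incomplete
#' leading/trailing phases are dropped.
#'
#' @param grf A filtered `grf_series` or numeric vector.
#' @param fs Sampling rate in Hz when `grf` is a bare vector.
#' @param threshold Force threshold in Newtons. Default 20.
#' @param min_phase Refractory period in seconds between accepted events.
#'   Default 0.05.
#' @return An object of class `gait_segmentation`: `heel_strikes` and
#'   `toe_offs` (sample indices, 1-based), `strides` (data frame with
#'   half-open `[heel_strike, toe_off)` stance and `[toe_off,
#'   next_heel_strike)` swing windows), and `fs`. Zero strides (with a
#'   warning) when no crossing is found.
#' @export
detect_events <- function(grf, fs = 1000, threshold = 20, min_phase = 0.05) {
  if (inherits(grf, "grf_series")) { fs <- grf$fs; grf <- grf$force }
  if (threshold <= 0) stop("detect_events: threshold must be positive")
  above <- grf > threshold
  d <- diff(above)
  ups <- which(d == 1L) + 1L    # first sample above threshold
  downs <- which(d == -1L) + 1L # first sample back below
  # merge, debounce against the previous accepted event of either kind
  ev <- rbind(
    if (length(ups)) data.frame(i = ups, type = "hs"),
    if (length(downs)) data.frame(i = downs, type = "to"))
  seg <- structure(list(heel_strikes = integer(), toe_offs = integer(),
                        strides = data.frame(stride = integer(),
                                             heel_strike = integer(),
                                             toe_off = integer(),
                                             next_heel_strike = integer()),
                        fs = fs), class = "gait_segmentation")
  if (is.null(ev) || !nrow(ev)) {
    warning("detect_events: no threshold crossings; empty segmentation")
    return(seg)
  }
  ev <- ev[order(ev$i), ]
  refractory <- round(min_phase * fs)
  keep <- logical(nrow(ev))
  last <- -Inf
  for (k in seq_len(nrow(ev))) {
    if (ev$i[k] - last >= refractory) { keep[k] <- TRUE; last <- ev$i[k] }
  }
  ev <- ev[keep, ]
  hs <- ev$i[ev$type == "hs"]; to <- ev$i[ev$type == "to"]
  # complete strides: hs_i < to < hs_{i+1}
  strides <- list()
  for (k in seq_along(hs)) {
    if (k == length(hs)) break
    t_in <- to[to > hs[k] & to < hs[k + 1]]
    if (length(t_in) != 1L) next
    strides[[length(strides) + 1L]] <-
      data.frame(heel_strike = hs[k], toe_off = t_in,
                 next_heel_strike = hs[k + 1])
  }
  if (length(strides)) {
    st <- do.call(rbind, strides)
    st <- cbind(stride = seq_len(nrow(st)), st)
    seg$strides <- st
    seg$heel_strikes <- hs
    seg$toe_offs <- to
  } else {
    warning("detect_events: crossings found but no complete stride")
    seg$heel_strikes <- hs
    seg$toe_offs <- to
  }
  seg
}

#' @export
print.gait_segmentation <- function(x, ...) {
  cat(sprintf("<gait_segmentation> %d complete stride(s) @ %g Hz\n",
              nrow(x$strides), x$fs))
  invisible(x)
}

#' Extract per-stride gait-phase windows from an EMG recording
#'
#' Cuts the recording into per-stride stance (`[heel_strike, toe_off)`) or
#' swing (`[toe_off, next_heel_strike)`) windows at the segmentation rate.
#' The EMG sampling rate must equal the segmentation rate (both 1000 Hz
#' after preprocessing), so force-plate event indices transfer one-to-one.
#'
#' @param rec An [emg_recording()].
#' @param seg A `gait_segmentation` from [detect_events()].
#' @param phase `"stance"` or `"swing"`.
#' @param n_strides Maximum number of strides to return, earliest first.
#'   Default 20.
#' @return A list of `emg_recording` windows, one per stride.
#' @export
extract_phase <- function(rec, seg, phase = c("stance", "swing"),
                          n_strides = 20L) {
  stopifnot(inherits(rec, "emg_recording"), inherits(seg, "gait_segmentation"))
  phase <- match.arg(phase)
  if (rec$fs != seg$fs)
    stop("extract_phase: EMG rate (", rec$fs,
         " Hz) does not match segmentation rate (", seg$fs, " Hz)")
  st <- seg$strides
  if (!nrow(st)) stop("extract_phase: segmentation contains no complete stride")
  st <- st[seq_len(min(nrow(st), n_strides)), , drop = FALSE]
  n <- ncol(rec$data)
  lapply(seq_len(nrow(st)), function(k) {
    win <- if (phase == "stance") c(st$heel_strike[k], st$toe_off[k])
           else c(st$toe_off[k], st$next_heel_strike[k])
    if (win[2] - 1L > n)
      stop("extract_phase: stride window extends past the recording")
    out <- rec
    out$data <- rec$data[, win[1]:(win[2] - 1L), drop = FALSE]
    out
  })
}

#' Export a gait segmentation as a delimited table
#'
#' Writes a 3-column tab-separated table (stride, heel_strike, toe_off).
#'
#' @param seg A `gait_segmentation`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  stopifnot(inherits(seg, "gait_segmentation"))
  utils::write.table(seg$strides[, c("stride", "heel_strike", "toe_off")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
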