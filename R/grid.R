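#' Electrode grid geometry
#'
#' Describes the rectangular HD-EMG electrode array: number of rows and
#' columns, the optional empty corner, and the inter-electrode pitch.
#' Columns run longitudinally along the muscle (proximal to distal within a
#' column, row 1 proximal). Electrodes are enumerated row-major: row 1
#' column 1, row 1 column 2, ..., skipping the missing corner, so that
#' electrode index and (row, col) coordinate map one-to-one.
#'
#' The default geometry is the 13-row by 5-column array with one empty
#' corner, giving 64 electrodes.
#'
#' @param n_rows Number of rows (>= 2). Default 13.
#' @param n_cols Number of columns (>= 1). Default 5.
#' @param missing_position `NULL` (full grid) or an integer `c(row, col)`
#'   naming one of the four corners left empty. Default `c(1, 1)`.
#' @param pitch_mm Inter-electrode spacing in millimetres. Default 8.
#' @return An object of class `electrode_grid` with fields `n_rows`,
#'   `n_cols`, `missing_position`, `pitch_mm`, `n_electrodes`, and the
#'   index maps `coord` (electrode x (row, col) matrix) and `index`
#'   (row x col matrix of electrode indices, `NA` at the empty corner).
#' @examples
#' g <- electrode_grid()          # 13 x 5, one empty corner: 64 electrodes
#' g$n_electrodes
#' nrow(differential_pairs(g))    # 59 longitudinal differential pairs
#' @export
electrode_grid <- function(n_rows = 13L, n_cols = 5L,
                           missing_position = c(1L, 1L), pitch_mm = 8) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 2L || n_cols < 1L)
    stop("electrode_grid: need n_rows >= 2 and n_cols >= 1")
  if (!is.null(missing_position)) {
    missing_position <- as.integer(missing_position)
    if (length(missing_position) != 2L)
      stop("electrode_grid: missing_position must be c(row, col) or NULL")
    corners <- rbind(c(1L, 1L), c(1L, n_cols), c(n_rows, 1L), c(n_rows, n_cols))
    if (!any(corners[, 1] == missing_position[1] & corners[, 2] == missing_position[2]))
      stop("electrode_grid: missing_position must be one of the four corners")
  }
  index <- matrix(NA_integer_, n_rows, n_cols)
  k <- 0L
  for (r in seq_len(n_rows)) for (c in seq_len(n_cols)) {
    if (!is.null(missing_position) &&
        r == missing_position[1] && c == missing_position[2]) next
    k <- k + 1L
    index[r, c] <- k
  }
  coord <- matrix(0L, k, 2L, dimnames = list(NULL, c("row", "col")))
  for (r in seq_len(n_rows)) for (c in seq_len(n_cols)) {
    i <- index[r, c]
    if (!is.na(i)) coord[i, ] <- c(r, c)
  }
  structure(list(
    n_rows = n_rows, n_cols = n_cols,
    missing_position = missing_position, pitch_mm = pitch_mm,
    n_electrodes = k, index = index, coord = coord
  ), class = "electrode_grid")
}

#' @export
print.electrode_grid <- function(x, ...) {
  miss <- if (is.null(x$missing_position)) "none" else
    sprintf("(%d, %d)", x$missing_position[1], x$missing_position[2])
  cat(sprintf(
    "<electrode_grid> %d x %d, pitch %g mm, missing corner %s: %d electrodes\n",
    x$n_rows, x$n_cols, x$pitch_mm, miss, x$n_electrodes))
  invisible(x)
}

#' Longitudinal differential pairs of an electrode grid
#'
#' Enumerates every pair of longitudinally adjacent electrodes (adjacent
#' rows, same column) where both electrodes exist. Ordering is
#' column-major, proximal to distal within each column, so pair k of a full
#' column spans rows (k, k+1). On the default 13 x 5 grid with one empty
#' corner this yields 59 pairs.
#'
#' @param grid An [electrode_grid()].
#' @return Integer matrix with one row per pair and columns `proximal`,
#'   `distal` (electrode indices), `row` (proximal row) and `col`.
#' @export
differential_pairs <- function(grid) {
  stopifnot(inherits(grid, "electrode_grid"))
  out <- list()
  k <- 0L
  for (c in seq_len(grid$n_cols)) for (r in seq_len(grid$n_rows - 1L)) {
    a <- grid$index[r, c]; b <- grid$index[r + 1L, c]
    if (is.na(a) || is.na(b)) next
    k <- k + 1L
    out[[k]] <- c(proximal = a, distal = b, row = r, col = c)
  }
  do.call(rbind, out)
}

#' EMG recording container
#'
#' A channels-by-samples matrix with its sampling rate, montage tag and a
#' per-channel validity mask. Monopolar recordings map one electrode per
#' channel (in grid enumeration order); differential recordings map one
#' longitudinal electrode pair per channel (in [differential_pairs()]
#' order).
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate in Hz.
#' @param montage `"monopolar"` or `"differential"`.
#' @param grid The [electrode_grid()] the channels live on, or `NULL`.
#' @param valid_mask Logical per channel; defaults to all `TRUE`.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(data, fs, montage = c("monopolar", "differential"),
                          grid = NULL, valid_mask = NULL) {
  montage <- match.arg(montage)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("emg_recording: fs must be a positive scalar (Hz)")
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, nrow(data))
  if (length(valid_mask) != nrow(data))
    stop("emg_recording: valid_mask length must equal channel count")
  if (!is.null(grid)) {
    expect <- if (montage == "monopolar") grid$n_electrodes
              else nrow(differential_pairs(grid))
    if (nrow(data) != expect)
      stop(sprintf(
        "emg_recording: %s montage on this grid needs %d channels, got %d",
        montage, expect, nrow(data)))
  }
  structure(list(data = data, fs = fs, montage = montage,
                 grid = grid, valid_mask = as.logical(valid_mask)),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d x %d %s channels @ %g Hz (%d valid)\n",
              nrow(x$data), ncol(x$data), x$montage, x$fs, sum(x$valid_mask)))
  invisible(x)
}

#' @export
dim.emg_recording <- function(x) dim(x$data)

#' Monopolar to longitudinal differential montage
#'
#' Computes the single differential along each grid column: each output
#' channel is distal electrode minus proximal electrode, sample-wise, one
#' channel per pair returned by [differential_pairs()]. A pair containing
#' an invalid monopolar channel is marked invalid.
#'
#' @param rec Monopolar [emg_recording()] consistent with `grid`.
#' @param grid The [electrode_grid()]; defaults to `rec$grid`.
#' @return Differential `emg_recording` with one channel per pair.
#' @export
to_differential <- function(rec, grid = rec$grid) {
  stopifnot(inherits(rec, "emg_recording"))
  if (rec$montage != "monopolar")
    stop("to_differential: input must be a monopolar recording")
  if (is.null(grid)) stop("to_differential: no grid supplied")
  if (nrow(rec$data) != grid$n_electrodes)
    stop("to_differential: channel count does not match grid electrode count")
  pairs <- differential_pairs(grid)
  d <- rec$data[pairs[, "distal"], , drop = FALSE] -
       rec$data[pairs[, "proximal"], , drop = FALSE]
  vm <- rec$valid_mask[pairs[, "distal"]] & rec$valid_mask[pairs[, "proximal"]]
  emg_recording(d, rec$fs, "differential", grid = grid, valid_mask = vm)
}

#' Read or write a grid descriptor as JSON
#'
#' Serializes the grid geometry as a small JSON block
#' `{rows, cols, missing, pitch_mm}` (`missing` is `[row, col]` or null).
#'
#' @param grid An [electrode_grid()].
#' @param path File path.
#' @return `write_grid_json` returns `path` invisibly; `read_grid_json`
#'   returns an `electrode_grid`.
#' @export
write_grid_json <- function(grid, path) {
  stopifnot(inherits(grid, "electrode_grid"))
  jsonlite::write_json(
    list(rows = grid$n_rows, cols = grid$n_cols,
         missing = grid$missing_position, pitch_mm = grid$pitch_mm),
    path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_grid_json
#' @export
read_grid_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  electrode_grid(x$rows, x$cols,
                 missing_position = if (is.null(x$missing) || !length(x$missing)) NULL
                                    else as.integer(x$missing),
                 pitch_mm = if (is.null(x$pitch_mm)) 8 else x$pitch_mm)
}
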