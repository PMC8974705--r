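#' Read and write EMG recordings
#'
#' Two on-disk formats are supported:
#'
#' * `"delimited"` — plain text, one channel per row, samples in columns,
#'   tab-separated, with a leading comment line `# fs=<Hz> montage=<tag>`.
#'   Lossless at the printed precision (15 significant digits).
#' * `"edf"` — European Data Format: 16-bit samples scaled into a declared
#'   physical range (default +/-5000 microvolts), the standard biosignal
#'   exchange container. Round-trip is exact to within one quantization
#'   step of the physical range.
#'
#' The channel count must match the grid montage: 64 monopolar channels or
#' 59 differential channels on the default 13 x 5 grid.
#'
#' @param path File path.
#' @param format `"delimited"` or `"edf"`.
#' @param grid An [electrode_grid()] used to validate the channel count and
#'   attach geometry; `NULL` skips the check.
#' @param fs Sampling rate in Hz, required for delimited files without a
#'   header line; ignored for EDF (taken from the file header).
#' @param montage Montage tag for delimited files without a header line.
#' @return `read_emg` returns an [emg_recording()]; `write_emg` returns
#'   `path` invisibly.
#' @export
read_emg <- function(path, format = c("delimited", "edf"), grid = NULL,
                     fs = NULL, montage = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_emg: no such file: ", path)
  rec <- if (format == "delimited") read_emg_delim(path, fs, montage)
         else read_emg_edf(path)
  if (!is.null(grid)) {
    n_mono <- grid$n_electrodes
    n_diff <- nrow(differential_pairs(grid))
    nc <- nrow(rec$data)
    inferred <- if (nc == n_mono) "monopolar" else if (nc == n_diff) "differential"
                else stop(sprintf(
      "read_emg: %s has %d channels; grid expects %d (monopolar) or %d (differential)",
      path, nc, n_mono, n_diff))
    if (is.null(rec$montage_tag)) rec$montage_tag <- inferred
    rec$grid <- grid
  }
  emg_recording(rec$data, rec$fs,
                montage = if (is.null(rec$montage_tag)) "monopolar" else rec$montage_tag,
                grid = rec$grid)
}

read_emg_delim <- function(path, fs, montage) {
  first <- readLines(path, n = 1L)
  hdr_fs <- hdr_montage <- NULL
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("fs=([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 2) hdr_fs <- as.numeric(m[2])
    m <- regmatches(first, regexec("montage=(\\w+)", first))[[1]]
    if (length(m) == 2) hdr_montage <- m[2]
  }
  fs <- if (!is.null(hdr_fs)) hdr_fs else fs
  if (is.null(fs)) stop("read_emg: ", path,
                        " has no '# fs=' header and no fs was supplied")
  dat <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#",
                                     colClasses = "numeric"))
  dimnames(dat) <- NULL
  if (!nrow(dat)) stop("read_emg: ", path, " contains no data rows")
  list(data = dat, fs = fs,
       montage_tag = if (!is.null(hdr_montage)) hdr_montage else montage,
       grid = NULL)
}

#' @rdname read_emg
#' @param rec The [emg_recording()] to write.
#' @param physical_range For EDF: symmetric physical amplitude range in
#'   microvolts mapped onto the 16-bit digital range. Default 5000
#'   (i.e. +/-5 mV).
#' @export
write_emg <- function(rec, path, format = c("delimited", "edf"),
                      physical_range = 5000) {
  stopifnot(inherits(rec, "emg_recording"))
  format <- match.arg(format)
  if (format == "delimited") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# fs=%.10g montage=%s", rec$fs, rec$montage), con)
    utils::write.table(format(rec$data, digits = 15, scientific = TRUE, trim = TRUE),
                       con, sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else {
    write_edf(rec$data, rec$fs, path, physical_range = physical_range,
              montage = rec$montage)
  }
  invisible(path)
}

# --- Minimal EDF (European Data Format) I/O -------------------------------
# Fixed-width ASCII headers (256 bytes global + 256 per signal), one data
# record holding the whole recording, 16-bit little-endian samples. The
# montage tag is carried in the 44-byte reserved header field.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(data, fs, path, physical_range = 5000,
                      montage = "monopolar") {
  ns <- nrow(data); n <- ncol(data)
  if (max(abs(data)) > physical_range)
    stop("write_edf: data exceed the declared physical range of +/-",
         physical_range, " uV")
  con <- file(path, "wb")
  on.exit(close(con))
  dur <- n / fs
  hdr <- paste0(
    edf_pad("0", 8),                      # version
    edf_pad("X X X X", 80),               # patient id (anonymous)
    edf_pad("Startdate X X X X", 80),     # recording id
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),           # header bytes
    edf_pad(sprintf("montage=%s fs=%.10g", montage, fs), 44),
    edf_pad(1, 8),                        # number of data records
    edf_pad(formatC(dur, format = "g", digits = 7), 8),
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(f, width)
    writeChar(paste0(vapply(f, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(sprintf("EMG ch%d", seq_len(ns)), 16)   # labels
  field(rep("", ns), 80)                        # transducer
  field(rep("uV", ns), 8)                       # physical dimension
  field(rep(formatC(-physical_range, format = "g"), ns), 8)
  field(rep(formatC(physical_range, format = "g"), ns), 8)
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("", ns), 80)                        # prefiltering
  field(rep(n, ns), 8)                          # samples per record
  field(rep("", ns), 32)                        # reserved
  scale <- 65535 / (2 * physical_range)
  dig <- round((t(data) + physical_range) * scale) - 32768
  writeBin(as.integer(as.vector(dig)), con, size = 2L, endian = "little")
  invisible(path)
}

read_emg_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8); rd(8)
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  rdv(16); rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8)); phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8)); dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  montage_tag <- NULL
  m <- regmatches(reserved, regexec("montage=(\\w+)", reserved))[[1]]
  if (length(m) == 2) montage_tag <- m[2]
  m <- regmatches(reserved, regexec("fs=([0-9.eE+-]+)", reserved))[[1]]
  fs_exact <- if (length(m) == 2) as.numeric(m[2]) else NA_real_
  out <- matrix(0, ns, sum(rep(spr[1], n_rec)))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[i], size = 2L,
                     endian = "little", signed = TRUE)
      phys <- phys_min[i] + (raw - dig_min[i]) *
        (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      out[i, (r - 1L) * spr[i] + seq_len(spr[i])] <- phys
    }
  }
  fs <- if (is.finite(fs_exact)) fs_exact else spr[1] / dur
  list(data = out, fs = fs, montage_tag = montage_tag, grid = NULL)
}

#' Read a vertical ground reaction force trace
#'
#' Delimited text with one sample per line (single column), or a labelled
#' table in which case the column named `fz`, `force` or `grf`
#' (case-insensitive) is used. A leading `# fs=<Hz>` comment line overrides
#' the `fs` argument.
#'
#' @param path File path.
#' @param fs Sampling rate in Hz when the file has no header. Default 1000.
#' @return A list of class `grf_series` with `force` (numeric vector,
#'   Newtons) and `fs`.
#' @export
read_grf <- function(path, fs = 1000) {
  if (!file.exists(path)) stop("read_grf: no such file: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("read_grf: ", path, " is empty")
  if (startsWith(lines[1], "#")) {
    m <- regmatches(lines[1], regexec("fs=([0-9.eE+-]+)", lines[1]))[[1]]
    if (length(m) == 2) fs <- as.numeric(m[2])
    lines <- lines[-1]
  }
  if (!length(lines)) stop("read_grf: ", path, " has a header but no data")
  lines <- trimws(lines)
  first <- strsplit(lines[1], "[\t,; ]+")[[1]]
  if (suppressWarnings(anyNA(as.numeric(first)))) {
    # labelled table: find the vertical-force column
    tab <- utils::read.table(text = lines, header = TRUE, sep = "",
                             comment.char = "#")
    hit <- grep("^(fz|force|grf)$", tolower(names(tab)))
    if (!length(hit)) stop("read_grf: ", path,
                           " has no column named fz/force/grf")
    force <- as.numeric(tab[[hit[1]]])
  } else {
    force <- as.numeric(vapply(strsplit(lines, "[\t,; ]+"),
                               function(x) x[1], ""))
  }
  structure(list(force = force, fs = fs), class = "grf_series")
}

#' @export
print.grf_series <- function(x, ...) {
  cat(sprintf("<grf_series> %d samples @ %g Hz, peak %.1f N\n",
              length(x$force), x$fs, max(x$force)))
  invisible(x)
}

#' Write a ground reaction force trace
#'
#' @param grf A `grf_series` (see [read_grf()]) or numeric vector.
#' @param path File path.
#' @param fs Sampling rate, used when `grf` is a bare vector.
#' @return `path`, invisibly.
#' @export
write_grf <- function(grf, path, fs = 1000) {
  if (inherits(grf, "grf_series")) { fs <- grf$fs; grf <- grf$force }
  writeLines(c(sprintf("# fs=%.10g", fs),
               format(grf, digits = 15, scientific = TRUE, trim = TRUE)), path)
  invisible(path)
}
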