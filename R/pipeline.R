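#' Run one EMG cleaning pipeline end to end
#'
#' Orchestrates the three processing routes on a monopolar 64-channel
#' recording plus its vertical ground reaction force:
#'
#' * **hpf** — downsample to the force-plate rate, longitudinal
#'   differential, 20 Hz zero-phase high-pass, statistical channel
#'   rejection, gait-phase extraction, spatial RMS map and band report.
#' * **pca** / **cca** — downsample, screen the monopolar channels,
#'   component decomposition + artifact-component flagging + spectral
#'   noise cancellation + reconstruction, interpolation of screened-out
#'   channels from grid neighbours, longitudinal differential, a second
#'   decomposition-cleaning pass on the differential data (without channel
#'   removal or interpolation), then the common tail: 20 Hz high-pass,
#'   channel rejection, phase extraction, maps and reports.
#'
#' Band decreases are always reported against the raw (downsampled,
#' unprocessed) differential data.
#'
#' @param emg Monopolar [emg_recording()] (native rate, e.g. 2048 Hz).
#' @param grf A `grf_series` (vertical force) or numeric vector at
#'   `target_fs`.
#' @param method `"hpf"`, `"pca"` or `"cca"`.
#' @param grid Electrode grid; defaults to the recording's.
#' @param target_fs Analysis rate (force-plate rate). Default 1000 Hz.
#' @param hp_cutoff High-pass cutoff in Hz. Default 20.
#' @param artifact_band Component-flagging band. Default `c(0, 20)` Hz.
#' @param cancel_band Band edited on flagged components. Default
#'   `c(0, 50)` Hz (the motion-artifact-associated bands).
#' @param phase Gait phase for the spatial map (`"stance"` or `"swing"`).
#' @param n_strides Maximum strides used. Default 20.
#' @param cca_lag CCA lag in samples. Default 1.
#' @param screen_z,flag_z Channel-screening and component-flagging
#'   z-thresholds. Defaults 3 and 2.
#' @param grf_threshold,grf_min_phase Event-detection parameters
#'   (Newtons, seconds).
#' @param bands Band-edge matrix for the band report.
#' @param seed Seed recorded in the provenance block (the pipeline itself
#'   is deterministic).
#' @return An object of class `pipeline_result`: `cleaned` (differential
#'   recording after the full route), `spatial_map`, `band_report`,
#'   `screening` (list of screening reports by stage), `flag_reports`
#'   (pca/cca only), `segmentation`, `method`, `provenance`.
#' @export
run_pipeline <- function(emg, grf, method = c("hpf", "pca", "cca"),
                         grid = emg$grid, target_fs = 1000, hp_cutoff = 20,
                         artifact_band = c(0, 20), cancel_band = c(0, 50),
                         phase = c("stance", "swing"), n_strides = 20L,
                         cca_lag = 1L, screen_z = 3, flag_z = 2,
                         grf_threshold = 20, grf_min_phase = 0.05,
                         bands = default_bands(), seed = NULL) {
  method <- match.arg(method)
  phase <- match.arg(phase)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  stopifnot(inherits(emg, "emg_recording"))
  if (emg$montage != "monopolar")
    stop("[input] run_pipeline expects a monopolar recording")
  if (is.null(grid)) stop("[input] no electrode grid available")
  if (anyNA(emg$data))
    stop("[input] recording contains NaN/NA samples (equipment malfunction?)")
  flat <- apply(emg$data, 1L, stats::sd) == 0
  if (any(flat))
    stop("[input] flatlined channel(s): ", paste(which(flat), collapse = ", "))

  screening <- list(); flag_reports <- list()

  ds <- stage("downsample", emg_downsample(emg, target_fs))
  raw_diff <- stage("differential", to_differential(ds, grid))

  if (method == "hpf") {
    work <- raw_diff
  } else {
    scr1 <- stage("screen_monopolar", screen_channels(ds, z_thresh = screen_z))
    screening$monopolar <- scr1
    cl1 <- stage("clean_monopolar",
                 clean_components(scr1$recording, method = method,
                                  lag = cca_lag, artifact_band = artifact_band,
                                  z_thresh = flag_z, cancel_band = cancel_band))
    flag_reports$monopolar <- cl1$flag_report
    interp <- stage("interpolate", interpolate_channels(cl1$recording, grid))
    diff1 <- stage("differential", to_differential(interp, grid))
    cl2 <- stage("clean_differential",
                 clean_components(diff1, method = method, lag = cca_lag,
                                  artifact_band = artifact_band,
                                  z_thresh = flag_z, cancel_band = cancel_band))
    flag_reports$differential <- cl2$flag_report
    work <- cl2$recording
  }

  hp <- stage("highpass", emg_highpass(work, cutoff = hp_cutoff))
  scr <- stage("channel_rejection", screen_channels(hp, z_thresh = screen_z))
  screening$differential <- scr
  hp <- scr$recording

  grf_f <- stage("grf_filter",
                 if (inherits(grf, "grf_series")) filter_grf(grf)
                 else filter_grf(grf, fs = target_fs))
  seg <- stage("gait_events",
               detect_events(grf_f, threshold = grf_threshold,
                             min_phase = grf_min_phase))
  wins <- stage("phase_extraction",
                extract_phase(hp, seg, phase = phase, n_strides = n_strides))
  smap <- stage("rms_map", rms_map(wins))
  brep <- stage("band_report", band_decrease(raw_diff, hp, bands = bands))

  prov <- list(method = method, seed = seed,
               params = list(target_fs = target_fs, hp_cutoff = hp_cutoff,
                             artifact_band = artifact_band,
                             cancel_band = cancel_band, phase = phase,
                             n_strides = n_strides, cca_lag = cca_lag,
                             screen_z = screen_z, flag_z = flag_z,
                             grf_threshold = grf_threshold,
                             grf_min_phase = grf_min_phase, bands = bands),
               package_version = as.character(utils::packageVersion("hdemgclean")),
               r_version = R.version.string)
  prov$config_hash <- object_hash(prov[c("method", "seed", "params")])

  structure(list(cleaned = hp, spatial_map = smap, band_report = brep,
                 screening = screening, flag_reports = flag_reports,
                 segmentation = seg, method = method, provenance = prov),
            class = "pipeline_result")
}

#' @rdname run_pipeline
#' @param ... Passed on to `run_pipeline`.
#' @export
run_hpf <- function(emg, grf, ...) run_pipeline(emg, grf, method = "hpf", ...)

#' @rdname run_pipeline
#' @export
run_component_method <- function(emg, grf, method = c("pca", "cca"), ...) {
  method <- match.arg(method)
  run_pipeline(emg, grf, method = method, ...)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> method=%s, %d strides, %d valid channels\n",
              x$method, nrow(x$segmentation$strides),
              sum(x$cleaned$valid_mask)))
  print(x$band_report)
  invisible(x)
}

# md5 of the serialized object; used for provenance / replay checks
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 3L), f)
  unname(tools::md5sum(f))
}

#' Hash of a pipeline result
#'
#' md5 over the serialized numeric content of a [run_pipeline()] result
#' (cleaned data, map, band report); identical input, configuration and
#' seed give an identical hash.
#'
#' @param result A `pipeline_result`.
#' @return A length-1 character md5 string.
#' @export
result_hash <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  object_hash(list(result$cleaned$data, result$cleaned$valid_mask,
                   result$spatial_map$values, result$band_report$pct_decrease))
}

#' Compare processing methods across subjects
#'
#' Assembles per-subject, per-method spatial maps into the
#' subjects x methods x locations array, runs the per-location
#' repeated-measures ANOVA with FDR correction ([location_anova()]), and
#' summarizes band reports side by side.
#'
#' @param results_by_subject A list (one element per subject) of named
#'   lists of `pipeline_result`s (or `spatial_map`s), one per method, with
#'   identical method names, grids and montages throughout.
#' @param alpha Significance level. Default 0.05.
#' @return A list of class `method_comparison`: `location_stats`,
#'   `band_summary` (mean percent decrease per method and band, when
#'   band reports are available), `methods`, `n_subjects`.
#' @export
compare_methods <- function(results_by_subject, alpha = 0.05) {
  if (length(results_by_subject) < 3L)
    stop("compare_methods: need at least 3 subjects")
  methods <- names(results_by_subject[[1]])
  if (length(methods) < 2L)
    stop("compare_methods: need at least 2 methods per subject")
  get_map <- function(x) if (inherits(x, "pipeline_result")) x$spatial_map else x
  ref <- get_map(results_by_subject[[1]][[1]])
  gr <- ref$grid
  L <- length(ref$values)
  n <- length(results_by_subject)
  arr <- array(NA_real_, c(n, length(methods), L))
  for (s in seq_len(n)) {
    if (!identical(sort(names(results_by_subject[[s]])), sort(methods)))
      stop("compare_methods: subject ", s, " has different method names")
    for (m in seq_along(methods)) {
      mp <- get_map(results_by_subject[[s]][[methods[m]]])
      if (!is.null(gr) && !is.null(mp$grid) &&
          !identical(mp$grid[c("n_rows", "n_cols", "missing_position")],
                     gr[c("n_rows", "n_cols", "missing_position")]))
        stop("compare_methods: grid mismatch for subject ", s,
             " method ", methods[m])
      if (length(mp$values) != L)
        stop("compare_methods: location count mismatch for subject ", s)
      arr[s, m, ] <- mp$values
    }
  }
  stats <- location_anova(arr, alpha = alpha)
  band_summary <- NULL
  first <- results_by_subject[[1]][[1]]
  if (inherits(first, "pipeline_result")) {
    rows <- list()
    for (m in methods) {
      reps <- lapply(results_by_subject, function(s) s[[m]]$band_report)
      pct <- sapply(reps, function(r) r$pct_decrease)
      rows[[m]] <- data.frame(method = m, band = reps[[1]]$band,
                              pct_decrease = rowMeans(pct),
                              se = apply(pct, 1L, stats::sd) / sqrt(n))
    }
    band_summary <- do.call(rbind, c(rows, make.row.names = FALSE))
  }
  structure(list(location_stats = stats, band_summary = band_summary,
                 methods = methods, n_subjects = n),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> %d subjects x %d methods: %d of %d locations significant\n",
              x$n_subjects, length(x$methods),
              sum(x$location_stats$significant, na.rm = TRUE),
              nrow(x$location_stats)))
  if (!is.null(x$band_summary)) print(x$band_summary)
  invisible(x)
}
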