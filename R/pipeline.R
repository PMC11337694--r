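#' @name pipeline
#' @title End-to-end run configuration and pipeline
NULL

psar_config_defaults <- function() {
  list(
    input = NULL,            # path to CSV/WFDB record (NULL: signal given in R)
    format = "auto",         # auto | csv | wfdb
    lead = NULL,             # lead selector for WFDB
    target_fs = 500,         # resample target (Hz); NULL disables
    preprocess = TRUE,       # wavelet denoise + LOESS detrend
    loess_span_s = 1.5,      # LOESS window (s)
    min_rr_s = 0.25,         # R-peak separation floor (s)
    split = "rr",            # rr | qrs | stpq
    mode = "circular",       # circular | truncated
    grid = 224,              # density grid size (rows = cols)
    u_range = NULL,          # explicit axis ranges (mV); NULL = adaptive
    v_range = NULL,
    normalize = "linear",    # linear | log
    window_s = NULL,         # windowing for export (s); NULL = whole record
    stride_s = NULL,         # window stride (s); default = window_s
    out_dir = ".",
    seed = NULL,
    log_level = "info"
  )
}

#' Build and validate a run configuration
#'
#' All pipeline options with validated values; unknown option names are
#' rejected. The configuration round-trips through JSON via
#' [read_config()] / [write_config()].
#'
#' @param ... Named options overriding the defaults (see
#'   `psar_config_defaults()` in the source for the full set: input paths,
#'   `target_fs`, `split`, `mode`, `grid`, normalization, windowing,
#'   `out_dir`, `seed`, ...).
#' @return A validated list of class `psar_config`.
#' @export
psar_config <- function(...) {
  defaults <- psar_config_defaults()
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(sprintf("Unknown config option(s): %s", paste(unknown, collapse = ", ")),
          class = "psar_error_config")
  }
  cfg <- utils::modifyList(defaults, user, keep.null = TRUE)
  if (!cfg$split %in% c("rr", "qrs", "stpq")) {
    abort("`split` must be rr, qrs or stpq.", class = "psar_error_config")
  }
  if (!cfg$mode %in% c("circular", "truncated")) {
    abort("`mode` must be circular or truncated.", class = "psar_error_config")
  }
  if (!cfg$normalize %in% c("linear", "log")) {
    abort("`normalize` must be linear or log.", class = "psar_error_config")
  }
  if (!is.null(cfg$target_fs) && cfg$target_fs <= 0) {
    abort("`target_fs` must be positive.", class = "psar_error_config")
  }
  if (cfg$grid < 1) abort("`grid` must be >= 1.", class = "psar_error_config")
  cfg <- cfg[names(defaults)]  # canonical key order for byte-stable round trips
  structure(cfg, class = "psar_config")
}

#' Read / write a run configuration (JSON)
#'
#' @param path JSON file path.
#' @return `read_config()` returns a validated `psar_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(psar_config, raw)
}

#' @rdname read_config
#' @param cfg A `psar_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "psar_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the full PSAR pipeline
#'
#' load -> resample (if needed) -> preprocess -> fiducials -> split -> embed
#' -> project -> density -> artifacts. Writes, under `cfg$out_dir`:
#' `<id>_density.png`, `<id>_density.csv` + `.json`, `<id>_fiducials.csv`
#' and `<id>_run.json` (run metadata incl. dropped-beat/segment counts).
#' Deterministic for a fixed config and input.
#'
#' @param cfg A [psar_config()].
#' @param signal Optional [ecg_signal()], bypassing `cfg$input`.
#' @param id Artifact basename (default `"record"`).
#' @return A list of class `psar_run`: `status` (0 ok, 2 degraded - fewer
#'   than 2 usable beats), `files`, `density`, `fiducials`, `n_beats`,
#'   `n_segments`.
#' @export
run_pipeline <- function(cfg, signal = NULL, id = "record") {
  stopifnot(inherits(cfg, "psar_config"))
  if (is.null(signal)) {
    if (is.null(cfg$input)) {
      abort("No input: set cfg$input or pass `signal`.", class = "psar_error_config")
    }
    signal <- load_signal(cfg$input, format = cfg$format, lead = cfg$lead)
  }
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)

  if (!is.null(cfg$target_fs) && signal$fs != cfg$target_fs) {
    signal <- resample_signal(signal, cfg$target_fs)
  }
  clean <- if (isTRUE(cfg$preprocess)) {
    preprocess_pipeline(signal, span_s = cfg$loess_span_s)
  } else signal

  fids <- detect_fiducials(clean, min_rr_s = cfg$min_rr_s)
  files <- character(0)
  f_fid <- file.path(cfg$out_dir, paste0(id, "_fiducials.csv"))
  write_fiducials_csv(fids, f_fid)
  files <- c(files, f_fid)

  traj <- suppressWarnings(
    reconstruct_attractor(clean, fids, method = cfg$split, mode = cfg$mode)
  )
  segs <- attr(traj, "segments")
  meta <- list(
    id = id, fs = clean$fs, n_samples = length(clean$samples),
    split = cfg$split, mode = cfg$mode,
    n_beats = nrow(fids), n_segments = nrow(segs),
    n_points = nrow(traj), normalized = cfg$normalize
  )
  if (nrow(traj) == 0L) {
    meta$status <- 2L
    f_meta <- file.path(cfg$out_dir, paste0(id, "_run.json"))
    jsonlite::write_json(meta, f_meta, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    inform(sprintf("run_pipeline[%s]: no segments; degraded result.", id))
    return(structure(list(status = 2L, files = c(files, f_meta),
                          density = NULL, fiducials = fids,
                          n_beats = nrow(fids), n_segments = 0L),
                     class = "psar_run"))
  }

  prj <- project_points(traj)
  dm <- make_density_map(prj, rows = cfg$grid, cols = cfg$grid,
                         u_range = cfg$u_range, v_range = cfg$v_range)
  dmn <- normalize_density(dm, mode = cfg$normalize)
  f_png <- file.path(cfg$out_dir, paste0(id, "_density.png"))
  render_image(dmn, f_png)
  f_grid <- write_density(dm, file.path(cfg$out_dir, paste0(id, "_density")))
  meta$status <- 0L
  meta$n_points_in <- dm$n_points_in
  meta$n_points_clipped <- dm$n_points_clipped
  meta$occupied_bins <- occupied_bins(dm)
  f_meta <- file.path(cfg$out_dir, paste0(id, "_run.json"))
  jsonlite::write_json(meta, f_meta, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  structure(list(status = 0L,
                 files = c(files, f_png, f_grid,
                           sub("csv$", "json", f_grid), f_meta),
                 density = dm, fiducials = fids,
                 n_beats = nrow(fids), n_segments = nrow(segs)),
            class = "psar_run")
}

#' @export
print.psar_run <- function(x, ...) {
  cat(sprintf("<psar_run> status %d: %d beats, %d segments, %d files\n",
              x$status, x$n_beats, x$n_segments, length(x$files)))
  invisible(x)
}

#' @export
glance.psar_run <- function(x, ...) {
  tibble::tibble(status = x$status, n_beats = x$n_beats,
                 n_segments = x$n_segments,
                 occupied_bins = if (!is.null(x$density))
                   occupied_bins(x$density) else 0L)
}

#' Export a labelled dataset of density images
#'
#' Builds a per-class directory tree of density PNGs (the usual image-folder
#' layout for downstream classifiers) plus a manifest CSV. With
#' `cfg$window_s` set, each record is cut into windows of that length
#' (stride `cfg$stride_s`, default the window length) and one image is
#' written per window.
#'
#' @param records A list; each element a list with `signal` (an
#'   [ecg_signal()]), `class` (label), and optional `id`. Records without a
#'   class label are skipped with a warning.
#' @param cfg A [psar_config()]; `out_dir` is the dataset root.
#' @return A tibble manifest (`record_id`, `class`, `split_method`,
#'   `window`, `path`), also written to `manifest.csv` in `out_dir`.
#' @export
export_dataset <- function(records, cfg) {
  stopifnot(inherits(cfg, "psar_config"))
  if (!length(records)) {
    abort("`records` must contain at least one record.",
          class = "psar_error_export")
  }
  rows <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    id <- rec$id %||% sprintf("rec%03d", i)
    if (is.null(rec$class) || is.na(rec$class) || !nzchar(rec$class)) {
      warn(sprintf("Record '%s' has no class label; skipped.", id))
      next
    }
    cls_dir <- file.path(cfg$out_dir, rec$class)
    if (!dir.exists(cls_dir)) dir.create(cls_dir, recursive = TRUE)
    sig <- rec$signal
    wins <- if (is.null(cfg$window_s)) {
      list(list(w = 0L, sig = sig))
    } else {
      stride <- cfg$stride_s %||% cfg$window_s
      n_w <- length(sig$samples) / sig$fs
      starts <- seq(0, n_w - cfg$window_s, by = stride)
      purrr::map(seq_along(starts), function(k) {
        i0 <- round(starts[k] * sig$fs) + 1L
        i1 <- i0 + round(cfg$window_s * sig$fs) - 1L
        list(w = k, sig = ecg_signal(sig$samples[i0:i1], sig$fs, sig$lead))
      })
    }
    for (wn in wins) {
      wid <- if (wn$w == 0L) id else sprintf("%s_w%02d", id, wn$w)
      sub_cfg <- cfg
      sub_cfg$out_dir <- cls_dir
      res <- run_pipeline(sub_cfg, signal = wn$sig, id = wid)
      if (res$status == 0L) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          record_id = id, class = rec$class, split_method = cfg$split,
          window = wn$w, path = file.path(cls_dir, paste0(wid, "_density.png"))
        )
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (!nrow(manifest)) {
    abort("No exportable records (all skipped or degraded).",
          class = "psar_error_export")
  }
  readr::write_csv(manifest, file.path(cfg$out_dir, "manifest.csv"))
  manifest
}
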