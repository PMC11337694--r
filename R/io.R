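#' @name io
#' @title Reading and writing signals and annotations
#'
#' @description
#' Two interchange formats are supported: two-column CSV (`time` s,
#' `amplitude` mV) and minimal WFDB records (text `.hea` header plus
#' little-endian `.dat`, formats 16 and 32). The WFDB writer uses format 32
#' with a gain of 1e6 ADC units/mV so amplitudes round-trip within 1e-6 mV.
NULL

#' Load a single-lead ECG
#'
#' @param path CSV file or WFDB record path (with or without `.hea`).
#' @param format `"auto"` (by extension), `"csv"` or `"wfdb"`.
#' @param lead Lead name to extract from a WFDB record (default the first
#'   signal). A lead absent from the record is an explicit error.
#' @return An [ecg_signal()] in mV.
#' @export
load_signal <- function(path, format = c("auto", "csv", "wfdb"), lead = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  switch(format, csv = read_signal_csv(path, lead = lead),
         wfdb = read_wfdb(path, lead = lead))
}

read_signal_csv <- function(path, lead = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "psar_error_io")
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (ncol(df) < 2L) {
    abort("CSV must have two columns: time (s), amplitude (mV).",
          class = "psar_error_io")
  }
  tt <- df[[1]]; amp <- df[[2]]
  if (length(tt) < 2L) abort("CSV too short.", class = "psar_error_io")
  dt <- diff(tt)
  dt0 <- stats::median(dt)
  if (dt0 <= 0 || any(abs(dt - dt0) > 1e-3 * dt0)) {
    abort("Non-uniform sampling in CSV time column.", class = "psar_error_io")
  }
  ecg_signal(amp, fs = 1 / dt0, lead = lead %||% "I", t0 = tt[1])
}

#' Write a signal as two-column CSV
#' @param sig An [ecg_signal()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_signal_csv <- function(sig, path) {
  assert_signal(sig)
  readr::write_csv(tidy(sig), path)
  invisible(path)
}

# strip a .hea/.dat extension to the record stem
wfdb_stem <- function(path) sub("\\.(hea|dat)$", "", path)

read_wfdb <- function(path, lead = NULL) {
  stem <- wfdb_stem(path)
  hea <- paste0(stem, ".hea")
  if (!file.exists(hea)) {
    abort(sprintf("WFDB header not found: %s", hea), class = "psar_error_io")
  }
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.double(top[3]) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig_lines <- lines[2:(1 + nsig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    gain_spec <- f[3]
    gain <- as.double(sub("\\(.*", "", sub("/.*", "", gain_spec)))
    baseline <- if (grepl("\\(", gain_spec)) {
      as.double(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_spec))
    } else 0
    list(file = f[1], fmt = as.integer(sub("x.*|:.*|\\+.*", "", f[2])),
         gain = if (is.na(gain) || gain == 0) 200 else gain,
         baseline = baseline,
         name = f[length(f)])
  }
  sigs <- lapply(sig_lines, parse_sig)
  names_ <- vapply(sigs, `[[`, "", "name")
  k <- if (is.null(lead)) 1L else match(lead, names_)
  if (is.na(k)) {
    abort(sprintf("Lead '%s' not in record (has: %s).", lead,
                  paste(names_, collapse = ", ")),
          class = "psar_error_io_lead")
  }
  fmt <- sigs[[k]]$fmt
  if (!fmt %in% c(16L, 32L)) {
    abort(sprintf("Unsupported WFDB format %d (only 16 and 32).", fmt),
          class = "psar_error_io")
  }
  dat <- file.path(dirname(hea), sigs[[k]]$file)
  size <- if (fmt == 16L) 2L else 4L
  raw_n <- file.info(dat)$size / size
  adc <- readBin(dat, "integer", n = raw_n, size = size, endian = "little",
                 signed = TRUE)
  # interleaved multiplexed samples
  adc <- adc[seq(k, length(adc), by = nsig)]
  if (!is.na(nsamp) && nsamp > 0) adc <- adc[seq_len(min(nsamp, length(adc)))]
  mv <- (adc - sigs[[k]]$baseline) / sigs[[k]]$gain
  ecg_signal(mv, fs = fs, lead = names_[k])
}

#' Write a signal as a minimal WFDB record
#'
#' Format 32, gain 1e6 ADC units/mV, baseline 0: quantization error is at
#' most 5e-7 mV, so reading the record back reproduces the amplitudes
#' within 1e-6 mV.
#'
#' @param sig An [ecg_signal()].
#' @param stem Record path without extension; writes `stem.hea` and
#'   `stem.dat`.
#' @return The header path, invisibly.
#' @export
write_wfdb <- function(sig, stem) {
  assert_signal(sig)
  gain <- 1e6
  adc <- as.integer(round(sig$samples * gain))
  rec <- basename(stem)
  hea <- paste0(stem, ".hea")
  writeLines(c(
    sprintf("%s 1 %.10g %d", rec, sig$fs, length(adc)),
    sprintf("%s.dat 32 %.10g(0)/mV 32 0 %d 0 0 %s", rec, gain, adc[1], sig$lead)
  ), hea)
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(adc, con, size = 4L, endian = "little")
  invisible(hea)
}

#' Write fiducial annotations as CSV
#'
#' Long format: `beat`, `wave`, `sample` (1-based), `time` (s).
#' @param fids An `ecg_fiducials` tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fiducials_csv <- function(fids, path) {
  stopifnot(inherits(fids, "ecg_fiducials"))
  readr::write_csv(tidy(fids), path)
  invisible(path)
}

#' Write a density map as CSV grid + JSON metadata
#'
#' The grid goes to `<stem>.csv` (rows x cols, no header; row 1 = lowest
#' `v` bin) and the metadata (ranges, counts, normalization) to
#' `<stem>.json`.
#' @param dm A `psar_density`.
#' @param stem Output path without extension.
#' @return The grid path, invisibly.
#' @export
write_density <- function(dm, stem) {
  stopifnot(inherits(dm, "psar_density"))
  grid_path <- paste0(stem, ".csv")
  readr::write_csv(as.data.frame(dm$grid), grid_path, col_names = FALSE)
  meta <- list(
    rows = nrow(dm$grid), cols = ncol(dm$grid),
    u_range = dm$u_range, v_range = dm$v_range,
    normalized = dm$normalized,
    n_points_in = dm$n_points_in, n_points_clipped = dm$n_points_clipped
  )
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(grid_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
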