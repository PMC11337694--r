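#' Uniformly sampled single-lead ECG trace
#'
#' `ecg_signal()` is the package's basic container: a numeric amplitude vector
#' in millivolts together with its sampling rate. The time of sample `k`
#' (1-based, the R convention used throughout the package) is
#' `t0 + (k - 1) / fs` seconds.
#'
#' @param samples Numeric vector of amplitudes (mV). Must be finite and
#'   non-empty.
#' @param fs Sampling rate in Hz (> 0).
#' @param lead Lead label, default `"I"`.
#' @param t0 Start offset in seconds, default 0.
#'
#' @return An object of class `ecg_signal`.
#' @examples
#' sig <- ecg_signal(sin(2 * pi * 1.25 * seq(0, 4, by = 1 / 500)), fs = 500)
#' sig
#' @export
ecg_signal <- function(samples, fs, lead = "I", t0 = 0) {
  samples <- as.double(samples)
  if (length(samples) < 1L) {
    abort("`samples` must contain at least one value.", class = "psar_error_signal")
  }
  if (!all(is.finite(samples))) {
    abort("`samples` must be finite (no NA/NaN/Inf).", class = "psar_error_signal")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).", class = "psar_error_signal")
  }
  structure(
    list(samples = samples, fs = as.double(fs),
         lead = as.character(lead), t0 = as.double(t0)),
    class = "ecg_signal"
  )
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> lead %s: %d samples @ %g Hz (%.3f s)\n",
              x$lead, length(x$samples), x$fs, duration_s(x)))
  cat(sprintf("  amplitude range [%.4g, %.4g] mV, t0 = %g s\n",
              min(x$samples), max(x$samples), x$t0))
  invisible(x)
}

#' @export
length.ecg_signal <- function(x) length(x$samples)

#' Duration of a signal in seconds
#' @param sig An [ecg_signal()].
#' @return Length of the record in seconds (`n / fs`).
#' @export
duration_s <- function(sig) length(sig$samples) / sig$fs

#' Sample times of a signal
#' @param sig An [ecg_signal()].
#' @return Numeric vector of times in seconds, one per sample.
#' @export
signal_times <- function(sig) sig$t0 + (seq_along(sig$samples) - 1) / sig$fs

#' @importFrom tibble as_tibble
#' @export
as_tibble.ecg_signal <- function(x, ...) {
  tibble::tibble(time = signal_times(x), amplitude = x$samples)
}

#' @export
tidy.ecg_signal <- function(x, ...) as_tibble.ecg_signal(x)

#' @export
glance.ecg_signal <- function(x, ...) {
  tibble::tibble(
    n = length(x$samples), fs = x$fs, lead = x$lead,
    duration_s = duration_s(x),
    mean_mv = mean(x$samples), sd_mv = stats::sd(x$samples),
    min_mv = min(x$samples), max_mv = max(x$samples)
  )
}

#' @export
autoplot.ecg_signal <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude (mV)",
                  title = sprintf("Lead %s @ %g Hz", object$lead, object$fs))
}

# internal: check an object is an ecg_signal
assert_signal <- function(sig, arg = "sig") {
  if (!inherits(sig, "ecg_signal")) {
    abort(sprintf("`%s` must be an <ecg_signal>.", arg), class = "psar_error_signal")
  }
  invisible(sig)
}
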