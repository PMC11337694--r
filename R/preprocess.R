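#' LOESS baseline-wander estimation and removal
#'
#' Baseline wander (respiration, electrode motion; < ~0.5 Hz) is estimated by
#' a local linear regression (LOESS, tricube weights, degree 1) fitted to the
#' low-frequency component of the signal and subtracted. The low-frequency
#' component is reconstructed from the coarse wavelet bands (the level-10
#' approximation together with detail levels `detail_min` ... 10, i.e. content
#' below roughly 2 Hz at 500 Hz); LOESS then smooths that component over a
#' `span_s`-second window so that in-band cardiac content (~1-2 Hz rhythms)
#' is not swallowed by the baseline estimate.
#'
#' `clean + baseline` reproduces the input exactly by construction.
#'
#' @param sig An [ecg_signal()], at least 2 s long.
#' @param span_s LOESS window in seconds (default 1.5 s; wander < 0.5 Hz).
#' @param levels Wavelet decomposition depth (default 10).
#' @param detail_min Coarsest detail levels `detail_min..levels` enter the
#'   trend component (default 8, the "D8-D10" scheme).
#' @return A list of class `psar_baseline` with elements `clean` and
#'   `baseline`, both [ecg_signal()]s.
#' @examples
#' sig <- add_drift(gen_sine(0.2, 400, duration_s = 20, fs = 500),
#'                  kind = "linear", value = 5e-05)
#' fit <- loess_baseline(sig)
#' @export
loess_baseline <- function(sig, span_s = 1.5, levels = 10L, detail_min = 8L) {
  assert_signal(sig)
  if (duration_s(sig) < 2) {
    abort("Record must be at least 2 s long for baseline estimation.",
          class = "psar_error_preprocess")
  }
  if (duration_s(sig) < span_s) {
    abort(sprintf("Record shorter than one LOESS window (%g s).", span_s),
          class = "psar_error_preprocess")
  }
  dec <- dwt_decompose(sig, levels = levels)
  keep <- c(paste0("D", seq(as.integer(detail_min), dec$levels)),
            paste0("A", dec$levels))
  low <- dwt_reconstruct(dec, keep = keep)

  # The trend component is band-limited (< ~2 Hz), so fit LOESS on a ~50 Hz
  # decimated grid and interpolate back: numerically equivalent, much faster.
  n <- length(sig$samples)
  dec_by <- max(1L, floor(sig$fs / 50))
  idx <- seq(1L, n, by = dec_by)
  tt <- (idx - 1) / sig$fs
  yy <- low$samples[idx]
  span_frac <- min(1, (span_s * sig$fs / dec_by) / length(idx))
  fit <- stats::loess(yy ~ tt, span = span_frac, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  base_dec <- stats::predict(fit, tt)
  t_full <- (seq_len(n) - 1) / sig$fs
  baseline <- stats::approx(tt, base_dec, xout = t_full, rule = 2)$y
  # remove only the time-varying trend: a constant level is not wander (it
  # is invisible to the (u,v) features and handled by the wavelet stage),
  # and subtracting it would distort signals with a one-sided waveform mean
  baseline <- baseline - mean(baseline)

  structure(
    list(
      clean = ecg_signal(sig$samples - baseline, sig$fs, sig$lead, sig$t0),
      baseline = ecg_signal(baseline, sig$fs, sig$lead, sig$t0)
    ),
    class = "psar_baseline"
  )
}

#' @export
print.psar_baseline <- function(x, ...) {
  cat("<psar_baseline>\n  $clean: "); print(x$clean)
  cat("  $baseline rms:", sqrt(mean(x$baseline$samples^2)), "mV\n")
  invisible(x)
}

#' @export
tidy.psar_baseline <- function(x, ...) {
  tibble::tibble(
    time = signal_times(x$clean),
    clean = x$clean$samples,
    baseline = x$baseline$samples
  )
}

#' Full preprocessing pipeline: denoise then detrend
#'
#' Composes [wavelet_denoise()] and [loess_baseline()]; returns the cleaned
#' signal. Length and sampling rate are preserved. Records not sampled at
#' 500 Hz should be passed through [resample_signal()] first so the wavelet
#' band labels keep their frequency meaning.
#'
#' @param sig An [ecg_signal()].
#' @param span_s LOESS window in seconds, passed to [loess_baseline()].
#' @param levels Wavelet depth for both stages (default 10).
#' @return The cleaned [ecg_signal()].
#' @export
preprocess_pipeline <- function(sig, span_s = 1.5, levels = 10L) {
  den <- wavelet_denoise(sig, levels = levels)
  loess_baseline(den, span_s = span_s, levels = levels)$clean
}

#' Band-limited resampling
#'
#' Fourier-domain resampling (as in the classic FFT resample): the spectrum
#' is truncated or zero-padded to the new length, with the Nyquist bin split
#' symmetrically, so the result is exactly band-limited. Output length is
#' `round(n * target_fs / fs)`.
#'
#' @param sig An [ecg_signal()].
#' @param target_fs Target sampling rate in Hz (> 0).
#' @return The resampled [ecg_signal()] with `fs = target_fs`.
#' @examples
#' sig80 <- gen_sine(0.2, 400, duration_s = 10, fs = 80)
#' sig500 <- resample_signal(sig80, 500)
#' @export
resample_signal <- function(sig, target_fs) {
  assert_signal(sig)
  if (!is.numeric(target_fs) || length(target_fs) != 1L ||
      !is.finite(target_fs) || target_fs <= 0) {
    abort("`target_fs` must be a single positive number (Hz).",
          class = "psar_error_preprocess")
  }
  n <- length(sig$samples)
  n_out <- as.integer(round(n * target_fs / sig$fs))
  if (n_out < 1L) {
    abort("Target rate too low: resampled signal would be empty.",
          class = "psar_error_preprocess")
  }
  if (n_out == n) {
    return(ecg_signal(sig$samples, target_fs, sig$lead, sig$t0))
  }
  X <- stats::fft(sig$samples)
  Y <- complex(length.out = n_out)
  # number of strictly-positive-frequency bins to carry over
  n_min <- min(n, n_out)
  half <- (n_min + 1L) %/% 2L  # bins 2..half are positive frequencies
  Y[1L] <- X[1L]
  if (half >= 2L) {
    Y[2:half] <- X[2:half]
    Y[n_out - (2:half) + 2L] <- X[n - (2:half) + 2L]
  }
  if (n_min %% 2L == 0L) {
    nyq <- half + 1L
    if (n_out > n) {
      # upsampling: split the old Nyquist bin between +/- frequencies
      Y[nyq] <- X[nyq] / 2
      Y[n_out - nyq + 2L] <- X[nyq] / 2
    } else {
      # downsampling: fold the symmetric pair into the new Nyquist bin
      Y[nyq] <- X[nyq] + X[n - nyq + 2L]
    }
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  ecg_signal(y, target_fs, sig$lead, sig$t0)
}
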