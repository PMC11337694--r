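#' @name synthetic
#' @title Synthetic test signals with exact ground truth
#'
#' @description
#' Ideal sinusoids (single and piecewise, matching the amplitudes/periods
#' used throughout the validation experiments), baseline-drift and noise
#' injectors, and a parameterised PQRST generator built from five Gaussian
#' bumps per beat with an exact fiducial table. Every generator is a pure
#' function of its arguments and seed.
NULL

#' Ideal half-period sinusoid
#'
#' `y(x) = A * sin(pi * x / half_period)` with `x` in milliseconds; one full
#' sine period spans `2 * half_period` ms. The canonical test signal is
#' `A = 0.2` mV, `half_period = 400` ms.
#'
#' @param A Amplitude in mV.
#' @param half_period Half period in ms (> 0).
#' @param duration_s Record length in seconds.
#' @param fs Sampling rate in Hz.
#' @return An [ecg_signal()].
#' @examples
#' gen_sine(0.2, 400, duration_s = 8, fs = 500)
#' @export
gen_sine <- function(A = 0.2, half_period = 400, duration_s = 8, fs = 500) {
  stopifnot(is.finite(A), half_period > 0, duration_s > 0, fs > 0)
  x_ms <- (seq_len(round(duration_s * fs)) - 1) / fs * 1000
  ecg_signal(A * sin(pi * x_ms / half_period), fs = fs, lead = "sine")
}

#' Piecewise two-period sinusoid
#'
#' Each composite period of `d1 + d2` ms holds one full sine cycle of
#' amplitude `A1` over the first `d1` ms and one of amplitude `A2` over the
#' remaining `d2` ms; each piece is phase-local (starts at zero at its own
#' boundary), so the composite is continuous. Defaults reproduce the
#' mixed-period test signal (`A1 = 0.1`, `A2 = 0.4` mV, `d1 = 800`,
#' `d2 = 1200` ms, composite period 2000 ms); set `A2 = A1` for the
#' equal-amplitude variant.
#'
#' @param A1,A2 Piece amplitudes in mV.
#' @param d1,d2 Piece durations in ms.
#' @param duration_s Record length in seconds.
#' @param fs Sampling rate in Hz.
#' @return An [ecg_signal()].
#' @export
gen_mixed_sine <- function(A1 = 0.1, A2 = 0.4, d1 = 800, d2 = 1200,
                           duration_s = 20, fs = 500) {
  stopifnot(d1 > 0, d2 > 0, duration_s > 0, fs > 0)
  x_ms <- (seq_len(round(duration_s * fs)) - 1) / fs * 1000
  xm <- x_ms %% (d1 + d2)
  first <- xm < d1
  y <- ifelse(first,
              A1 * sin(pi * xm / (d1 / 2)),
              A2 * sin(pi * (xm - d1) / (d2 / 2)))
  ecg_signal(y, fs = fs, lead = "mixed_sine")
}

#' Add baseline drift
#'
#' @param sig An [ecg_signal()].
#' @param kind `"constant"` (adds `value` mV everywhere) or `"linear"`
#'   (adds `value * t_ms` mV; `value` in mV per millisecond). The canonical
#'   drift cases are a 0.1 mV constant and a 5e-5 mV/ms ramp.
#' @param value Offset (mV) or slope (mV/ms).
#' @return The drifted [ecg_signal()].
#' @export
add_drift <- function(sig, kind = c("constant", "linear"), value) {
  kind <- match.arg(kind)
  assert_signal(sig)
  t_ms <- (seq_along(sig$samples) - 1) / sig$fs * 1000
  drift <- switch(kind, constant = rep(value, length(t_ms)),
                  linear = value * t_ms)
  ecg_signal(sig$samples + drift, sig$fs, sig$lead, sig$t0)
}

#' Add white and/or powerline noise
#'
#' @param sig An [ecg_signal()].
#' @param white_sd Std. dev. of additive white Gaussian noise (mV).
#' @param snr_db If given, overrides `white_sd` so the white-noise power
#'   sits `snr_db` dB below the clean signal power.
#' @param powerline_amp,powerline_hz Amplitude (mV) and frequency (Hz) of an
#'   additive mains sinusoid (default 0 mV at 50 Hz).
#' @param seed Integer seed; fixes the white noise exactly.
#' @return The noisy [ecg_signal()].
#' @export
add_noise <- function(sig, white_sd = 0, snr_db = NULL,
                      powerline_amp = 0, powerline_hz = 50, seed = NULL) {
  assert_signal(sig)
  n <- length(sig$samples)
  if (!is.null(snr_db)) {
    white_sd <- sqrt(mean(sig$samples^2)) * 10^(-snr_db / 20)
  }
  noise <- numeric(n)
  if (white_sd > 0) {
    noise <- noise + if (is.null(seed)) rnorm(n, 0, white_sd) else
      withr::with_seed(seed, rnorm(n, 0, white_sd))
  }
  if (powerline_amp > 0) {
    tt <- signal_times(sig)
    noise <- noise + powerline_amp * sin(2 * pi * powerline_hz * tt)
  }
  ecg_signal(sig$samples + noise, sig$fs, sig$lead, sig$t0)
}

#' Default PQRST morphology table
#'
#' Lead-I-like defaults: R ~1 mV, P < 0.25 mV, Q/S small and negative, T
#' broad and positive. Edit a copy to change morphology (e.g. zero the P
#' amplitude to emulate absent P waves).
#'
#' @return A tibble with columns `wave`, `offset_ms`, `amp_mv`, `sd_ms`.
#' @export
default_waves <- function() {
  tibble::tibble(
    wave = c("p", "q", "r", "s", "t"),
    offset_ms = c(-170, -25, 0, 30, 300),
    amp_mv = c(0.15, -0.10, 1.00, -0.15, 0.30),
    sd_ms = c(25, 8, 10, 8, 45)
  )
}

#' Synthetic PQRST ECG with exact ground truth
#'
#' Each beat is a sum of five Gaussian bumps (P, Q, R, S, T) at configurable
#' offsets, amplitudes and widths; RR intervals are drawn from a lognormal
#' with mean `60000 / bpm` ms and coefficient of variation `rr_cv`
#' (`rr_cv = 0` gives a perfectly regular rhythm; ~0.15 emulates a clearly
#' irregular one). Intervals are clamped to `[0.5, 2] x` the mean to avoid
#' physiologically absurd draws. Optional drift and noise are applied last.
#'
#' @param bpm Mean heart rate (default 60).
#' @param rr_cv RR-interval coefficient of variation (default 0).
#' @param duration_s Record length in seconds (default 10).
#' @param fs Sampling rate in Hz (default 500).
#' @param waves Morphology table as in `default_waves()`: columns `wave`,
#'   `offset_ms`, `amp_mv`, `sd_ms`.
#' @param drift `NULL` or `list(kind =, value =)` for [add_drift()].
#' @param noise `NULL` or a list of arguments for [add_noise()].
#' @param first_beat_s Time of the first R peak (default 0.5 s).
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `psar_synth_ecg`: `signal` (the [ecg_signal()]),
#'   `truth` (exact `ecg_fiducials`), `rr_ms` (drawn RR series), `waves`.
#' @examples
#' ecg <- gen_synthetic_ecg(bpm = 60, duration_s = 10, seed = 42)
#' glance(ecg$truth)
#' @export
gen_synthetic_ecg <- function(bpm = 60, rr_cv = 0, duration_s = 10, fs = 500,
                              waves = default_waves(), drift = NULL,
                              noise = NULL, first_beat_s = 0.5, seed = NULL) {
  stopifnot(bpm > 0, rr_cv >= 0, duration_s > 0, fs > 0)
  mean_rr <- 60000 / bpm
  w <- waves[match(c("p", "q", "r", "s", "t"), waves$wave), ]
  span_after <- w$offset_ms[5] + 2 * w$sd_ms[5]   # T tail
  span_before <- -w$offset_ms[1] + 2 * w$sd_ms[1] # P lead-in
  if (span_after + span_before >= mean_rr) {
    abort(sprintf(
      "Wave offsets span %.0f ms and overlap the adjacent beat at a mean RR of %.0f ms.",
      span_after + span_before, mean_rr), class = "psar_error_synth")
  }

  dur_ms <- duration_s * 1000
  draw <- function() {
    r_times <- first_beat_s * 1000
    repeat {
      rr <- if (rr_cv > 0) {
        sdlog <- sqrt(log1p(rr_cv^2))
        x <- rlnorm(1, meanlog = log(mean_rr) - sdlog^2 / 2, sdlog = sdlog)
        min(max(x, 0.5 * mean_rr), 2 * mean_rr)
      } else mean_rr
      nxt <- r_times[length(r_times)] + rr
      if (nxt > dur_ms - span_after) break
      r_times <- c(r_times, nxt)
    }
    r_times
  }
  r_times <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())

  n <- round(duration_s * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  y <- numeric(n)
  for (b in r_times) {
    for (k in seq_len(nrow(w))) {
      ctr <- b + w$offset_ms[k]
      sdk <- w$sd_ms[k]
      lo <- max(1L, floor((ctr - 5 * sdk) / 1000 * fs) + 1L)
      hi <- min(n, ceiling((ctr + 5 * sdk) / 1000 * fs) + 1L)
      if (hi >= lo) {
        rng <- lo:hi
        y[rng] <- y[rng] + w$amp_mv[k] * exp(-(t_ms[rng] - ctr)^2 / (2 * sdk^2))
      }
    }
  }
  sig <- ecg_signal(y, fs = fs, lead = "I")
  if (!is.null(drift)) sig <- add_drift(sig, drift$kind, drift$value)
  if (!is.null(noise)) {
    sig <- do.call(add_noise, c(list(sig = sig), noise,
                                if (is.null(noise$seed) && !is.null(seed))
                                  list(seed = seed + 1L)))
  }

  to_idx <- function(off) {
    i <- as.integer(round((r_times + off) / 1000 * fs)) + 1L
    i[i < 1L | i > n] <- NA_integer_
    i
  }
  truth <- tibble::tibble(
    beat = seq_along(r_times),
    p = if (w$amp_mv[1] != 0) to_idx(w$offset_ms[1]) else NA_integer_,
    q = if (w$amp_mv[2] != 0) to_idx(w$offset_ms[2]) else NA_integer_,
    r = to_idx(0),
    s = if (w$amp_mv[4] != 0) to_idx(w$offset_ms[4]) else NA_integer_,
    t = if (w$amp_mv[5] != 0) to_idx(w$offset_ms[5]) else NA_integer_
  )
  structure(
    list(signal = sig, truth = new_fiducials(truth, fs, n),
         rr_ms = diff(r_times), waves = w),
    class = "psar_synth_ecg"
  )
}

#' @export
print.psar_synth_ecg <- function(x, ...) {
  cat(sprintf("<psar_synth_ecg> %d beats, mean RR %.0f ms\n",
              nrow(x$truth), mean(x$rr_ms)))
  print(x$signal)
  invisible(x)
}
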