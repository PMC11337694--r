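#' @name fiducials
#' @title PQRST fiducial detection
#'
#' @description
#' R peaks are found on a smoothed-curvature (squared second difference)
#' transform with an adaptive rolling threshold, then refined to the raw
#' local maximum; Q, S, P and T are located in physiology-standard windows
#' around each R peak. All windows and thresholds are exposed as arguments.
#' Fiducial tables are tibbles with one row per beat and 1-based sample
#' indices (`NA` = wave not reliably present).
NULL

# centered moving average, edges shrunk to the available window
moving_avg <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# blockwise rolling max: threshold context over ~win samples
rolling_max_block <- function(x, win) {
  n <- length(x)
  bs <- max(1L, win %/% 2L)
  nb <- ceiling(n / bs)
  blk <- vapply(seq_len(nb), function(b) {
    max(x[((b - 1L) * bs + 1L):min(b * bs, n)])
  }, numeric(1))
  ctx <- vapply(seq_len(nb), function(b) {
    max(blk[max(1L, b - 1L):min(nb, b + 1L)])
  }, numeric(1))
  rep(ctx, each = bs, length.out = n)
}

# local maxima indices of x (strict rise, non-strict fall)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
}

# greedy min-separation enforcement: keep larger score, earlier on ties
enforce_separation <- function(idx, score, min_sep) {
  if (length(idx) <= 1L) return(idx)
  ord <- order(-score, idx)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(idx[i] - kept) >= min_sep)) kept <- c(kept, idx[i])
  }
  sort(kept)
}

#' Detect R peaks
#'
#' @param sig A preprocessed [ecg_signal()] (drift-free; see
#'   [preprocess_pipeline()]).
#' @param min_rr_s Minimum separation between accepted peaks in seconds
#'   (default 0.25 s, i.e. 240 bpm ceiling).
#' @param threshold Fraction of the rolling-window curvature maximum a
#'   candidate must exceed (default 0.4).
#' @param floor_frac Global floor as a fraction of the overall curvature
#'   maximum (default 0.1). All thresholds scale with the signal, so
#'   detection is invariant to positive amplitude rescaling.
#' @param refine_ms Half-width of the raw-signal refinement window (40 ms).
#'
#' @return Integer vector of 1-based R-peak sample indices (possibly empty).
#' @examples
#' ecg <- gen_synthetic_ecg(bpm = 60, duration_s = 10, seed = 1)
#' detect_r_peaks(ecg$signal)
#' @export
detect_r_peaks <- function(sig, min_rr_s = 0.25, threshold = 0.4,
                           floor_frac = 0.1, refine_ms = 40) {
  assert_signal(sig)
  s <- sig$samples
  n <- length(s)
  fs <- sig$fs
  if (n < 5L || all(s == 0)) return(integer(0))

  # curvature transform: squared second difference of a 5-point smooth,
  # integrated over ~QRS width
  sm <- moving_avg(s, 5L)
  curv <- c(0, diff(sm, differences = 2L), 0)^2
  d <- moving_avg(curv, max(3L, round(0.05 * fs)))
  gmax <- max(d)
  if (gmax <= 0) return(integer(0))

  thr <- pmax(threshold * rolling_max_block(d, round(2 * fs)),
              floor_frac * gmax)
  cand <- local_maxima(d)
  cand <- cand[d[cand] >= thr[cand]]
  # filter edge transients: a beat this close to the record boundary cannot
  # be delineated anyway
  guard <- round(0.1 * fs)
  cand <- cand[cand > guard & cand <= n - guard]
  if (!length(cand)) return(integer(0))

  min_sep <- round(min_rr_s * fs)
  peaks <- enforce_separation(cand, d[cand], min_sep)

  refine <- function(p) {
    w <- max(1L, as.integer(round(refine_ms / 1000 * fs)))
    lo <- max(1L, p - w); hi <- min(n, p + w)
    as.integer(lo + which.max(s[lo:hi]) - 1L)
  }
  peaks <- unique(vapply(peaks, refine, integer(1)))
  peaks <- enforce_separation(peaks, s[peaks], min_sep)

  # re-detection pass: look again inside suspiciously long RR gaps with a
  # locally scaled threshold (missed low-amplitude beats)
  if (length(peaks) >= 3L) {
    med_rr <- stats::median(diff(peaks))
    added <- integer(0)
    for (i in seq_len(length(peaks) - 1L)) {
      gap <- peaks[i + 1L] - peaks[i]
      if (gap > 1.8 * med_rr) {
        lo <- peaks[i] + min_sep
        hi <- peaks[i + 1L] - min_sep
        if (hi > lo) {
          seg <- lo:hi
          c2 <- local_maxima(d[seg])
          if (length(c2)) {
            c2 <- seg[c2]
            best <- c2[which.max(d[c2])]
            if (d[best] >= 0.25 * threshold * max(d[peaks[i]], d[peaks[i + 1L]])) {
              added <- c(added, refine(best))
            }
          }
        }
      }
    }
    if (length(added)) {
      peaks <- sort(unique(c(peaks, added)))
      peaks <- enforce_separation(peaks, s[peaks], min_sep)
    }
  }
  as.integer(peaks)
}

# extremum index helpers over a (possibly empty) window
win_extremum <- function(s, lo, hi, what = c("max", "min", "absmax")) {
  what <- match.arg(what)
  if (hi < lo) return(NA_integer_)
  w <- s[lo:hi]
  k <- switch(what, max = which.max(w), min = which.min(w),
              absmax = which.max(abs(w)))
  lo + k - 1L
}

wave_prominent <- function(s, idx, lo, hi, floor) {
  if (is.na(idx)) return(NA_integer_)
  if (abs(s[idx] - stats::median(s[lo:hi])) < floor) return(NA_integer_)
  idx
}

#' Locate Q, S, T and P waves around detected R peaks
#'
#' Search windows (all configurable, defaults in ms): Q = signed minimum in
#' (R-80, R); S = signed minimum in (R, R+80); T = largest-|amplitude|
#' extremum in (S+40, S+400), clipped to the next beat; P = maximum in
#' (Q-250, Q-40), clipped past the previous beat's T. A wave whose deviation
#' from the local median is below `prominence_floor` is reported `NA`.
#'
#' @param sig The [ecg_signal()] the peaks were detected on.
#' @param r_peaks Integer vector of R-peak indices from [detect_r_peaks()].
#' @param prominence_floor Minimum |amplitude - local median| in mV for a
#'   wave to count as present (default 0.05 mV).
#' @param qs_ms,t_min_ms,t_max_ms,p_min_ms,p_max_ms Window edges in ms.
#' @return An `ecg_fiducials` tibble: columns `beat`, `p`, `q`, `r`, `s`,
#'   `t` (1-based sample indices, `NA` = missing), with the sampling rate in
#'   `attr(, "fs")`.
#' @export
refine_fiducials <- function(sig, r_peaks, prominence_floor = 0.05,
                             qs_ms = 80, t_min_ms = 40, t_max_ms = 400,
                             p_min_ms = 40, p_max_ms = 250) {
  assert_signal(sig)
  r_peaks <- as.integer(r_peaks)
  n <- length(sig$samples)
  fs <- sig$fs
  if (length(r_peaks) == 0L) {
    return(new_fiducials(tibble::tibble(
      beat = integer(0), p = integer(0), q = integer(0),
      r = integer(0), s = integer(0), t = integer(0)), fs, n))
  }
  if (is.unsorted(r_peaks, strictly = TRUE) || any(r_peaks < 1L | r_peaks > n)) {
    abort("`r_peaks` must be strictly increasing indices within the signal.",
          class = "psar_error_fiducials")
  }
  ms <- function(x) as.integer(round(x / 1000 * fs))
  sgl <- sig$samples
  nb <- length(r_peaks)
  p_idx <- q_idx <- s_idx <- t_idx <- rep(NA_integer_, nb)

  for (i in seq_len(nb)) {
    r <- r_peaks[i]
    # Q: signed minimum just before R
    lo <- max(1L, r - ms(qs_ms)); hi <- r - 1L
    q <- win_extremum(sgl, lo, hi, "min")
    if (!is.na(q)) q <- wave_prominent(sgl, q, lo, hi, prominence_floor)
    # S: signed minimum just after R
    lo <- r + 1L; hi <- min(n, r + ms(qs_ms))
    s_ <- win_extremum(sgl, lo, hi, "min")
    if (!is.na(s_)) s_ <- wave_prominent(sgl, s_, lo, hi, prominence_floor)
    # T: largest-|amplitude| extremum after S, clipped to next beat
    if (!is.na(s_)) {
      lo <- s_ + ms(t_min_ms)
      hi <- min(n, s_ + ms(t_max_ms))
      if (i < nb) hi <- min(hi, r_peaks[i + 1L] - 1L)
      t_ <- win_extremum(sgl, lo, hi, "absmax")
      if (!is.na(t_)) t_ <- wave_prominent(sgl, t_, max(1L, lo), hi, prominence_floor)
      t_idx[i] <- t_
    }
    # P: maximum before Q, clipped past the previous beat's T
    if (!is.na(q)) {
      lo <- max(1L, q - ms(p_max_ms))
      hi <- q - ms(p_min_ms)
      if (i > 1L && !is.na(t_idx[i - 1L])) lo <- max(lo, t_idx[i - 1L] + 1L)
      p <- win_extremum(sgl, lo, hi, "max")
      if (!is.na(p)) p <- wave_prominent(sgl, p, lo, max(lo, hi), prominence_floor)
      p_idx[i] <- p
    }
    q_idx[i] <- q
    s_idx[i] <- s_
  }

  out <- tibble::tibble(beat = seq_len(nb), p = p_idx, q = q_idx,
                        r = r_peaks, s = s_idx, t = t_idx)
  # enforce the within-beat ordering invariant P < Q < R < S < T
  out$q[!is.na(out$q) & out$q >= out$r] <- NA_integer_
  out$s[!is.na(out$s) & out$s <= out$r] <- NA_integer_
  out$p[!is.na(out$p) & !is.na(out$q) & out$p >= out$q] <- NA_integer_
  out$p[is.na(out$q)] <- NA_integer_
  out$t[!is.na(out$t) & !is.na(out$s) & out$t <= out$s] <- NA_integer_
  out$t[is.na(out$s)] <- NA_integer_
  new_fiducials(out, fs, n)
}

new_fiducials <- function(df, fs, n_samples) {
  structure(df, fs = fs, n_samples = as.integer(n_samples),
            class = c("ecg_fiducials", class(tibble::tibble())))
}

#' Build a fiducial table by hand
#'
#' For experiments where beat boundaries are known analytically (ideal
#' sinusoids, external annotations) rather than detected. Missing wave
#' columns are filled with `NA`.
#'
#' @param df Data frame with at least a column `r` of strictly increasing
#'   1-based R indices; optional `p`, `q`, `s`, `t` columns.
#' @param fs Sampling rate in Hz.
#' @param n_samples Length of the signal the indices refer to.
#' @return An `ecg_fiducials` tibble.
#' @examples
#' as_fiducials(data.frame(r = seq(1, 4001, by = 400)), fs = 500,
#'              n_samples = 5000)
#' @export
as_fiducials <- function(df, fs, n_samples) {
  df <- tibble::as_tibble(df)
  if (!"r" %in% names(df)) {
    abort("`df` must have a column `r`.", class = "psar_error_fiducials")
  }
  if (is.unsorted(df$r, strictly = TRUE)) {
    abort("R indices must be strictly increasing.",
          class = "psar_error_fiducials")
  }
  for (w in c("p", "q", "s", "t")) {
    if (!w %in% names(df)) df[[w]] <- NA_integer_
    df[[w]] <- as.integer(df[[w]])
  }
  df$r <- as.integer(df$r)
  if (any(df$r < 1L | df$r > n_samples)) {
    abort("R indices out of signal bounds.", class = "psar_error_fiducials")
  }
  df$beat <- seq_len(nrow(df))
  new_fiducials(df[, c("beat", "p", "q", "r", "s", "t")], fs, n_samples)
}

#' Detect all fiducials in one call
#'
#' Convenience wrapper: [detect_r_peaks()] then [refine_fiducials()].
#' @inheritParams detect_r_peaks
#' @param ... Passed to [refine_fiducials()].
#' @return An `ecg_fiducials` tibble.
#' @export
detect_fiducials <- function(sig, min_rr_s = 0.25, ...) {
  refine_fiducials(sig, detect_r_peaks(sig, min_rr_s = min_rr_s), ...)
}

#' Keep only beats usable by a split method
#'
#' The three split schemes need different waves: `"rr"` needs only R (always
#' present); `"qrs"` needs Q and S; `"stpq"` needs S (to end a segment) or Q
#' (to start one) - beats with neither are dropped. Drop counts are reported
#' with a message.
#'
#' @param fids An `ecg_fiducials` tibble.
#' @param method One of `"rr"`, `"qrs"`, `"stpq"`.
#' @return The filtered `ecg_fiducials` tibble.
#' @export
validate_beats <- function(fids, method = c("rr", "qrs", "stpq")) {
  method <- match.arg(method)
  stopifnot(inherits(fids, "ecg_fiducials"))
  keep <- switch(method,
    rr = !is.na(fids$r),
    qrs = !is.na(fids$q) & !is.na(fids$s),
    stpq = !is.na(fids$q) | !is.na(fids$s)
  )
  dropped <- sum(!keep)
  if (dropped > 0) {
    inform(sprintf("validate_beats: dropped %d of %d beats for method '%s'.",
                   dropped, nrow(fids), method))
  }
  new_fiducials(fids[keep, , drop = FALSE], attr(fids, "fs"),
                attr(fids, "n_samples"))
}

#' @export
glance.ecg_fiducials <- function(x, ...) {
  fs <- attr(x, "fs")
  rr <- diff(x$r) / fs
  tibble::tibble(
    n_beats = nrow(x),
    mean_rr_s = if (length(rr)) mean(rr) else NA_real_,
    cv_rr = if (length(rr) > 1) stats::sd(rr) / mean(rr) else NA_real_,
    mean_hr_bpm = if (length(rr)) 60 / mean(rr) else NA_real_,
    prop_p = mean(!is.na(x$p)), prop_q = mean(!is.na(x$q)),
    prop_s = mean(!is.na(x$s)), prop_t = mean(!is.na(x$t))
  )
}

#' @export
tidy.ecg_fiducials <- function(x, ...) {
  fs <- attr(x, "fs")
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(cols = c("p", "q", "r", "s", "t"),
                        names_to = "wave", values_to = "sample") |>
    dplyr::filter(!is.na(.data$sample)) |>
    dplyr::mutate(time = (.data$sample - 1) / fs)
}

#' Plot a signal with its fiducial marks
#' @param sig An [ecg_signal()].
#' @param fids The matching `ecg_fiducials` tibble.
#' @return A ggplot object.
#' @export
plot_fiducials <- function(sig, fids) {
  marks <- tidy(fids)
  marks$amplitude <- sig$samples[marks$sample]
  autoplot(sig) +
    ggplot2::geom_point(data = marks,
                        ggplot2::aes(x = .data$time, y = .data$amplitude,
                                     colour = .data$wave), size = 1.6) +
    ggplot2::labs(colour = "wave")
}
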