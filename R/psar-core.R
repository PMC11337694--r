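#' @name psar_core
#' @title Periodic split attractor reconstruction
#'
#' @description
#' The reconstruction splits the signal into cardiac-cycle segments, embeds
#' each segment in 3-D by Takens time-delay embedding with its own delay
#' `tau = round(T/3)` (one third of that segment's period), and re-splices
#' the per-cycle trajectories. Three split schemes are provided:
#'
#' * `"rr"`   - segments between consecutive R peaks (contiguous cover);
#' * `"qrs"`  - the QRS complex, from Q to S of each beat;
#' * `"stpq"` - S of one beat to Q of the next (the T-P stretch).
#'
#' In `"circular"` mode (the default) the delayed indices wrap within the
#' cycle, i.e. the segment is treated as one period of a periodic orbit;
#' this is what makes a single-cycle sinusoid's orbit exactly invariant
#' under cyclic permutation of the three coordinates (Z3 symmetry) and the
#' point set invariant under time-rescaling of the cycle. `"truncated"`
#' mode drops the last `2*tau` samples instead of wrapping.
NULL

#' Delay parameter for a split period
#'
#' `tau = round(T/3)`, rounding half away from zero, with a floor of 1
#' sample. Vectorised.
#'
#' @param period_samples Integer segment length(s) in samples (>= 3).
#' @return Integer delay(s) in samples.
#' @examples
#' compute_tau(900) # 300
#' compute_tau(400) # 133
#' @export
compute_tau <- function(period_samples) {
  period_samples <- as.integer(period_samples)
  if (any(period_samples < 3L)) {
    abort("`period_samples` must be >= 3 to admit a delay of T/3.",
          class = "psar_error_split")
  }
  pmax(1L, as.integer(floor(period_samples / 3 + 0.5)))
}

#' Split a fiducial table into cycle segments
#'
#' Segments are half-open `[start, end)` in 1-based sample indices:
#' `"rr"` gives `[R[i-1], R[i])` for consecutive beats, `"qrs"` gives
#' `[Q[i], S[i])` per beat, `"stpq"` gives `[S[i-1], Q[i])` for consecutive
#' beat pairs. Segments shorter than `min_len` samples are dropped (with a
#' message); each retained segment carries its period and `tau`.
#'
#' @param fids An `ecg_fiducials` tibble (run [validate_beats()] first).
#' @param method `"rr"`, `"qrs"` or `"stpq"`.
#' @param min_len Minimum segment length in samples (default 9, so that
#'   `tau >= 3`).
#' @return A `psar_segments` tibble: `cycle_id`, `start`, `end`,
#'   `period_samples`, `tau_samples`, `method`.
#' @export
split_cycles <- function(fids, method = c("rr", "qrs", "stpq"), min_len = 9L) {
  method <- match.arg(method)
  stopifnot(inherits(fids, "ecg_fiducials"))
  fs <- attr(fids, "fs")
  empty <- tibble::tibble(cycle_id = integer(0), start = integer(0),
                          end = integer(0), period_samples = integer(0),
                          tau_samples = integer(0), method = character(0))
  if (nrow(fids) < 2L) {
    return(new_segments(empty, fs, method))
  }
  seg <- switch(method,
    rr = {
      r <- fids$r[!is.na(fids$r)]
      tibble::tibble(start = r[-length(r)], end = r[-1L])
    },
    qrs = {
      ok <- !is.na(fids$q) & !is.na(fids$s)
      tibble::tibble(start = fids$q[ok], end = fids$s[ok])
    },
    stpq = {
      s_prev <- fids$s[-nrow(fids)]
      q_next <- fids$q[-1L]
      ok <- !is.na(s_prev) & !is.na(q_next)
      tibble::tibble(start = s_prev[ok], end = q_next[ok])
    }
  )
  seg <- seg[seg$end > seg$start, , drop = FALSE]
  seg$period_samples <- seg$end - seg$start
  short <- seg$period_samples < min_len
  if (any(short)) {
    inform(sprintf("split_cycles: dropped %d segment(s) shorter than %d samples.",
                   sum(short), min_len))
    seg <- seg[!short, , drop = FALSE]
  }
  if (!nrow(seg)) return(new_segments(empty, fs, method))
  seg$tau_samples <- compute_tau(seg$period_samples)
  seg$cycle_id <- seq_len(nrow(seg))
  seg$method <- method
  new_segments(seg[, c("cycle_id", "start", "end", "period_samples",
                       "tau_samples", "method")], fs, method)
}

new_segments <- function(df, fs, method) {
  structure(df, fs = fs, method = method,
            class = c("psar_segments", class(tibble::tibble())))
}

#' Delay-embed one cycle segment
#'
#' Embeds the segment samples `y[0..T-1]` as 3-D points
#' `(y[n], y[n+tau], y[n+2*tau])`. In `"circular"` mode indices wrap modulo
#' the segment length (T points); in `"truncated"` mode no wrap is used and
#' the trajectory has `max(0, T - 2*tau)` points.
#'
#' @param sig The [ecg_signal()] the segment indexes into.
#' @param seg One row of a `psar_segments` tibble (or any list with
#'   `start`, `end`, `tau_samples`).
#' @param mode `"circular"` (default) or `"truncated"`.
#' @param tau_override Optional integer delay replacing the segment's own
#'   `tau` (used for delay-sweep experiments over `[0, 2T]`).
#' @param cycle_id Cycle label attached to the points (default 1).
#' @return A `psar_trajectory` tibble with columns `x`, `y`, `z`,
#'   `cycle_id`.
#' @export
embed_segment <- function(sig, seg, mode = c("circular", "truncated"),
                          tau_override = NULL, cycle_id = 1L) {
  mode <- match.arg(mode)
  assert_signal(sig)
  start <- as.integer(seg$start); end <- as.integer(seg$end)
  if (is.na(start) || is.na(end) || start < 1L ||
      end > length(sig$samples) + 1L || end <= start) {
    abort("Segment out of signal bounds.", class = "psar_error_embed")
  }
  tt <- end - start
  tau <- if (!is.null(tau_override)) as.integer(tau_override) else
    as.integer(seg$tau_samples)
  if (is.na(tau) || tau < 0L) {
    abort("Invalid delay `tau`.", class = "psar_error_embed")
  }
  yv <- sig$samples[start:(end - 1L)]
  if (mode == "circular") {
    n0 <- 0:(tt - 1L)
    pts <- tibble::tibble(
      x = yv[n0 + 1L],
      y = yv[(n0 + tau) %% tt + 1L],
      z = yv[(n0 + 2L * tau) %% tt + 1L],
      cycle_id = as.integer(cycle_id)
    )
  } else {
    keep <- tt - 2L * tau
    if (keep <= 0L) {
      warn(sprintf("Segment of %d samples too short for truncated embedding with tau = %d; empty trajectory.",
                   tt, tau))
      pts <- tibble::tibble(x = double(0), y = double(0), z = double(0),
                            cycle_id = integer(0))
    } else {
      n0 <- 0:(keep - 1L)
      pts <- tibble::tibble(
        x = yv[n0 + 1L],
        y = yv[n0 + tau + 1L],
        z = yv[n0 + 2L * tau + 1L],
        cycle_id = as.integer(cycle_id)
      )
    }
  }
  new_trajectory(pts, fs = sig$fs, mode = mode)
}

new_trajectory <- function(df, fs, mode) {
  structure(df, fs = fs, mode = mode,
            class = c("psar_trajectory", class(tibble::tibble())))
}

#' Reconstruct the full split attractor
#'
#' Runs [validate_beats()], [split_cycles()] and [embed_segment()] over the
#' whole record and concatenates the per-cycle trajectories in cycle order.
#' Each segment is embedded with its own `tau = round(period/3)`.
#'
#' @inheritParams split_cycles
#' @param sig The [ecg_signal()] the fiducials refer to.
#' @param mode Embedding mode, `"circular"` (default) or `"truncated"`.
#' @param min_len Minimum segment length in samples.
#' @return A `psar_trajectory` tibble (`x`, `y`, `z`, `cycle_id`) with the
#'   segment table in `attr(, "segments")`. Empty (with a warning) when no
#'   usable segments exist.
#' @examples
#' ecg <- gen_synthetic_ecg(bpm = 60, duration_s = 10, seed = 1)
#' fid <- detect_fiducials(ecg$signal)
#' traj <- reconstruct_attractor(ecg$signal, fid, method = "rr")
#' @export
reconstruct_attractor <- function(sig, fids, method = c("rr", "qrs", "stpq"),
                                  mode = c("circular", "truncated"),
                                  min_len = 9L) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  assert_signal(sig)
  fids <- validate_beats(fids, method)
  segs <- split_cycles(fids, method, min_len = min_len)
  if (!nrow(segs)) {
    warn("No usable segments; returning an empty trajectory.")
    out <- new_trajectory(tibble::tibble(x = double(0), y = double(0),
                                         z = double(0), cycle_id = integer(0)),
                          fs = sig$fs, mode = mode)
    attr(out, "segments") <- segs
    return(out)
  }
  parts <- purrr::map(seq_len(nrow(segs)), function(i) {
    embed_segment(sig, segs[i, ], mode = mode, cycle_id = segs$cycle_id[i])
  })
  pts <- dplyr::bind_rows(parts)
  out <- new_trajectory(pts, fs = sig$fs, mode = mode)
  attr(out, "segments") <- segs
  out
}

#' @export
glance.psar_trajectory <- function(x, ...) {
  segs <- attr(x, "segments")
  tibble::tibble(
    n_points = nrow(x),
    n_cycles = length(unique(x$cycle_id)),
    mode = attr(x, "mode"),
    method = if (!is.null(segs)) attr(segs, "method") else NA_character_,
    mean_period = if (!is.null(segs) && nrow(segs)) mean(segs$period_samples) else NA_real_,
    mean_tau = if (!is.null(segs) && nrow(segs)) mean(segs$tau_samples) else NA_real_
  )
}

#' @export
autoplot.psar_trajectory <- function(object, ...) {
  prj <- project_points(object)
  ggplot2::ggplot(tibble::as_tibble(prj),
                  ggplot2::aes(x = .data$u, y = .data$v,
                               group = .data$cycle_id)) +
    ggplot2::geom_path(alpha = 0.4, linewidth = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "u (mV)", y = "v (mV)")
}
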