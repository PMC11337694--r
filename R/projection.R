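#' Project a trajectory onto the plane orthogonal to x = y = z
#'
#' Orthonormal change of basis with third axis `(1,1,1)/sqrt(3)`:
#' `u = (x - z)/sqrt(2)`, `v = (x - 2y + z)/sqrt(6)`,
#' `w = (x + y + z)/sqrt(3)`. A constant offset added to the signal moves
#' every embedded point along `(1,1,1)` and therefore changes only `w`:
#' the in-plane coordinates `(u, v)` - and any density map built from them -
#' are exactly invariant to constant baseline shifts.
#'
#' @param traj A `psar_trajectory` tibble (columns `x`, `y`, `z`,
#'   `cycle_id`).
#' @return A `psar_projection` tibble with columns `u`, `v`, `w`,
#'   `cycle_id`.
#' @export
project_points <- function(traj) {
  if (!all(c("x", "y", "z") %in% names(traj))) {
    abort("`traj` must have columns x, y, z.", class = "psar_error_project")
  }
  out <- tibble::tibble(
    u = (traj$x - traj$z) / sqrt(2),
    v = (traj$x - 2 * traj$y + traj$z) / sqrt(6),
    w = (traj$x + traj$y + traj$z) / sqrt(3),
    cycle_id = if ("cycle_id" %in% names(traj)) traj$cycle_id
               else rep(1L, nrow(traj))
  )
  structure(out, fs = attr(traj, "fs"), mode = attr(traj, "mode"),
            class = c("psar_projection", class(tibble::tibble())))
}

#' Bin projected points into a 2-D density map
#'
#' A plain 2-D histogram of `(u, v)`: bins are half-open `[lo, hi)` with the
#' top edge inclusive, row 1 of the grid is the lowest `v` bin. When no
#' range is given, a symmetric range of `+/- 1.05 * max(|u|, |v|)` is used
#' (adaptive per record); pass explicit ranges to compare maps bin-for-bin
#' across records.
#'
#' @param pts A `psar_projection` tibble.
#' @param rows,cols Grid size (default 224 x 224, sized for image
#'   classifiers).
#' @param u_range,v_range Length-2 numeric axis bounds in mV, or `NULL` for
#'   the adaptive symmetric default.
#' @param upsample Temporal upsampling factor `k` (default 1 = none). For
#'   orbits whose points are sparse relative to the grid (few samples per
#'   cycle), `k - 1` linearly interpolated points are inserted between
#'   consecutive trajectory points of the same cycle before binning, so the
#'   map measures the traced curve rather than the sample positions.
#' @return A `psar_density` object: integer `grid` (rows x cols),
#'   `u_range`, `v_range`, `normalized`, `n_points_in`, `n_points_clipped`.
#' @export
make_density_map <- function(pts, rows = 224L, cols = 224L,
                             u_range = NULL, v_range = NULL, upsample = 1L) {
  if (upsample > 1L && nrow(pts) > 1L) pts <- upsample_trajectory(pts, upsample)
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) {
    abort("`rows` and `cols` must be >= 1.", class = "psar_error_density")
  }
  if (is.null(u_range) || is.null(v_range)) {
    if (!nrow(pts)) {
      abort("Empty point set with no explicit ranges.",
            class = "psar_error_density")
    }
    r <- 1.05 * max(abs(c(pts$u, pts$v)))
    if (r <= 0) r <- 1  # degenerate all-at-origin cloud
    if (is.null(u_range)) u_range <- c(-r, r)
    if (is.null(v_range)) v_range <- c(-r, r)
  }
  u_range <- as.double(u_range); v_range <- as.double(v_range)
  if (length(u_range) != 2L || length(v_range) != 2L ||
      !all(is.finite(c(u_range, v_range))) ||
      u_range[2] <= u_range[1] || v_range[2] <= v_range[1]) {
    abort("Ranges must be finite with max > min.", class = "psar_error_density")
  }
  grid <- matrix(0L, nrow = rows, ncol = cols)
  n_in <- 0L; n_clip <- 0L
  if (nrow(pts)) {
    iu <- floor((pts$u - u_range[1]) / (u_range[2] - u_range[1]) * cols)
    iv <- floor((pts$v - v_range[1]) / (v_range[2] - v_range[1]) * rows)
    iu[pts$u == u_range[2]] <- cols - 1  # top edge inclusive
    iv[pts$v == v_range[2]] <- rows - 1
    ok <- iu >= 0 & iu < cols & iv >= 0 & iv < rows
    n_in <- sum(ok); n_clip <- sum(!ok)
    if (n_in) {
      idx <- as.integer(iu[ok]) * rows + as.integer(iv[ok]) + 1L
      grid <- matrix(tabulate(idx, nbins = rows * cols), nrow = rows)
    }
  }
  structure(
    list(grid = grid, u_range = u_range, v_range = v_range,
         normalized = FALSE, n_points_in = as.integer(n_in),
         n_points_clipped = as.integer(n_clip)),
    class = "psar_density"
  )
}

# linear interpolation of (u, v) along the point sequence, per cycle
upsample_trajectory <- function(pts, k) {
  k <- as.integer(k)
  parts <- split(seq_len(nrow(pts)), pts$cycle_id)
  res <- purrr::map(parts, function(ii) {
    m <- length(ii)
    if (m < 2L) return(pts[ii, , drop = FALSE])
    xo <- seq(1, m, by = 1 / k)
    tibble::tibble(
      u = stats::approx(seq_len(m), pts$u[ii], xout = xo)$y,
      v = stats::approx(seq_len(m), pts$v[ii], xout = xo)$y,
      w = stats::approx(seq_len(m), pts$w[ii], xout = xo)$y,
      cycle_id = pts$cycle_id[ii[1]]
    )
  })
  dplyr::bind_rows(res)
}

#' Normalize a density map
#'
#' @param dm A `psar_density`.
#' @param mode `"linear"` (`grid / max`) or `"log"`
#'   (`log1p(grid) / log1p(max)`, monotone in the counts). An all-zero map
#'   is returned unchanged (no NaN).
#' @return The normalized `psar_density` (`max(grid) == 1` when nonempty).
#' @export
normalize_density <- function(dm, mode = c("linear", "log")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dm, "psar_density"))
  mx <- max(dm$grid)
  if (mx > 0) {
    dm$grid <- switch(mode,
      linear = dm$grid / mx,
      log = log1p(dm$grid) / log1p(mx)
    )
    dm$normalized <- TRUE
  }
  dm
}

#' Number of occupied (nonzero) bins
#' @param dm A `psar_density`.
#' @return Integer count of bins with nonzero mass.
#' @export
occupied_bins <- function(dm) sum(dm$grid > 0)

#' @export
print.psar_density <- function(x, ...) {
  cat(sprintf("<psar_density> %d x %d grid, %d points in, %d clipped%s\n",
              nrow(x$grid), ncol(x$grid), x$n_points_in, x$n_points_clipped,
              if (x$normalized) ", normalized" else ""))
  cat(sprintf("  u range [%.4g, %.4g] mV, v range [%.4g, %.4g] mV, %d occupied bins\n",
              x$u_range[1], x$u_range[2], x$v_range[1], x$v_range[2],
              occupied_bins(x)))
  invisible(x)
}

#' @export
tidy.psar_density <- function(x, ...) {
  rows <- nrow(x$grid); cols <- ncol(x$grid)
  du <- diff(x$u_range) / cols; dv <- diff(x$v_range) / rows
  tibble::tibble(
    u = rep(x$u_range[1] + (seq_len(cols) - 0.5) * du, each = rows),
    v = rep(x$v_range[1] + (seq_len(rows) - 0.5) * dv, times = cols),
    density = as.vector(x$grid)
  )
}

#' @export
glance.psar_density <- function(x, ...) {
  tibble::tibble(
    rows = nrow(x$grid), cols = ncol(x$grid),
    n_points_in = x$n_points_in, n_points_clipped = x$n_points_clipped,
    occupied_bins = occupied_bins(x), normalized = x$normalized,
    max_density = max(x$grid)
  )
}

#' @export
autoplot.psar_density <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$u, y = .data$v, fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "u (mV)", y = "v (mV)", fill = "density")
}
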