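#' @name dwt
#' @title Periodized orthogonal discrete wavelet transform (Daubechies-6)
#'
#' @description
#' The denoising scheme used here separates an ECG into dyadic frequency
#' bands with a 10-level Daubechies-6 (db6) decomposition and discards whole
#' bands: the level-10 approximation `A10` (roughly < 0.24 Hz at 500 Hz,
#' baseline) and the two finest detail bands `D1`, `D2` (roughly > 62.5 Hz,
#' powerline and muscle noise). No coefficient thresholding is applied.
#'
#' The transform is a periodized orthogonal filter bank: the signal is
#' symmetrically extended to a multiple of `2^levels`, analysed with circular
#' convolution, and inverted exactly by the transposed operator, so the
#' round-trip error is at machine precision.
NULL

# db6 scaling (low-pass analysis) filter, 12 taps.
# Computed by spectral factorization of the Daubechies polynomial with 6
# vanishing moments; satisfies sum(h) = sqrt(2), sum(h^2) = 1 and
# orthogonality to its even shifts (QMF conditions, re-checked in the tests).
DB6_LO <- c(
   1.1154074335010937e-01,  4.9462389039845289e-01,
   7.5113390802109470e-01,  3.1525035170919852e-01,
  -2.2626469396543963e-01, -1.2976686756726183e-01,
   9.7501605587322987e-02,  2.7522865530305664e-02,
  -3.1582039317486002e-02,  5.5384220116150718e-04,
   4.7772575109455038e-03, -1.0773010853084789e-03
)

# matching high-pass: g[m] = (-1)^m h[L-1-m]
DB6_HI <- rev(DB6_LO) * rep_len(c(1, -1), length(DB6_LO))

# one analysis step on an even-length vector, circular extension
dwt_step <- function(x, lo = DB6_LO, hi = DB6_HI) {
  n <- length(x)
  n2 <- n %/% 2L
  a <- numeric(n2)
  d <- numeric(n2)
  base <- 2L * (seq_len(n2) - 1L)
  for (m in seq_along(lo)) {
    xv <- x[(base + (m - 1L)) %% n + 1L]
    a <- a + lo[m] * xv
    d <- d + hi[m] * xv
  }
  list(a = a, d = d)
}

# one synthesis step (transpose of dwt_step; exact inverse for orthonormal
# filters, also when the filter wraps more than once)
idwt_step <- function(a, d, lo = DB6_LO, hi = DB6_HI) {
  n <- 2L * length(a)
  x <- numeric(n)
  base <- 2L * (seq_along(a) - 1L)
  for (m in seq_along(lo)) {
    idx <- (base + (m - 1L)) %% n + 1L
    x[idx] <- x[idx] + lo[m] * a + hi[m] * d
  }
  x
}

#' Decompose a signal into a wavelet coefficient pyramid
#'
#' @param sig An [ecg_signal()].
#' @param levels Decomposition depth `j` (default 10, the depth whose band
#'   labels A10/D1/D2 carry the intended frequency meaning at 500 Hz).
#' @param wavelet Wavelet family; only `"db6"` is provided.
#'
#' @details The signal is extended by symmetric reflection of its tail to the
#' next multiple of `2^levels` and analysed with a periodized filter bank.
#' A signal shorter than `2^levels` samples cannot be decomposed that deep;
#' the error names the maximum feasible depth `floor(log2(n))`.
#'
#' @return An object of class `ecg_dwt` with elements `approx` (level-j
#'   approximation), `details` (list `D1` ... `Dj`, `D1` finest), `levels`,
#'   `wavelet`, and bookkeeping needed for exact inversion.
#' @seealso [dwt_reconstruct()], [wavelet_denoise()]
#' @export
dwt_decompose <- function(sig, levels = 10L, wavelet = "db6") {
  assert_signal(sig)
  if (!identical(wavelet, "db6")) {
    abort("Only the 'db6' wavelet is supported.", class = "psar_error_dwt")
  }
  levels <- as.integer(levels)
  if (levels < 1L) abort("`levels` must be >= 1.", class = "psar_error_dwt")
  n <- length(sig$samples)
  if (n < 2^levels) {
    abort(sprintf(
      "Signal of %d samples is too short for a %d-level decomposition; maximum feasible depth is %d.",
      n, levels, max(0L, floor(log2(n)))
    ), class = "psar_error_dwt")
  }
  block <- 2^levels
  x <- sig$samples
  if (n %% block == 0) {
    # already periodizable without extension
    n_pad <- n
  } else {
    # mirror-periodic extension (period 2n, endpoints repeated): the
    # periodic continuation seen by the circular filter bank is continuous,
    # so ramps and offsets do not create junction artifacts
    n_pad <- as.integer(ceiling(2 * n / block) * block)
    pos <- (n + seq_len(n_pad - n) - 1L) %% (2L * n)
    ext <- ifelse(pos < n, pos + 1L, 2L * n - pos)
    x <- c(x, x[ext])
  }
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    st <- dwt_step(a)
    details[[j]] <- st$d
    a <- st$a
  }
  names(details) <- paste0("D", seq_len(levels))
  structure(
    list(wavelet = wavelet, levels = levels, approx = a, details = details,
         n = n, n_pad = n_pad, fs = sig$fs, lead = sig$lead, t0 = sig$t0),
    class = "ecg_dwt"
  )
}

#' @export
print.ecg_dwt <- function(x, ...) {
  cat(sprintf("<ecg_dwt> %s, %d levels, %d samples (padded to %d)\n",
              x$wavelet, x$levels, x$n, x$n_pad))
  invisible(x)
}

#' @export
tidy.ecg_dwt <- function(x, ...) {
  bands <- c(names(x$details), paste0("A", x$levels))
  coefs <- c(x$details, list(x$approx))
  purrr::map2_dfr(bands, coefs, function(b, v) {
    tibble::tibble(band = b, k = seq_along(v) - 1L, coefficient = v)
  })
}

#' Invert a wavelet decomposition
#'
#' @param dec An `ecg_dwt` from [dwt_decompose()], possibly with bands zeroed.
#' @param keep Optional character vector of band names to keep (e.g.
#'   `c("D3", "D4", "A10")`); all other bands are zeroed before inversion.
#'   `NULL` (default) keeps everything.
#' @return An [ecg_signal()] of the original length.
#' @export
dwt_reconstruct <- function(dec, keep = NULL) {
  if (!inherits(dec, "ecg_dwt")) {
    abort("`dec` must be an <ecg_dwt>.", class = "psar_error_dwt")
  }
  approx <- dec$approx
  details <- dec$details
  if (!is.null(keep)) {
    valid <- c(names(details), paste0("A", dec$levels))
    bad <- setdiff(keep, valid)
    if (length(bad)) {
      abort(sprintf("Unknown band(s): %s", paste(bad, collapse = ", ")),
            class = "psar_error_dwt")
    }
    if (!(paste0("A", dec$levels) %in% keep)) approx <- approx * 0
    for (b in names(details)) {
      if (!(b %in% keep)) details[[b]] <- details[[b]] * 0
    }
  }
  a <- approx
  for (j in rev(seq_len(dec$levels))) {
    a <- idwt_step(a, details[[j]])
  }
  ecg_signal(a[seq_len(dec$n)], fs = dec$fs, lead = dec$lead, t0 = dec$t0)
}

#' Wavelet band-removal denoising
#'
#' Removes the level-`levels` approximation (baseline band) and the finest
#' detail bands from the signal: at 500 Hz with the default 10-level db6
#' scheme this drops content below ~0.24 Hz (A10) and above ~62.5 Hz (D1,
#' D2) while passing the diagnostic ECG band essentially unchanged. The
#' operation is linear in the signal.
#'
#' @param sig An [ecg_signal()]; use [resample_signal()] to bring records to
#'   500 Hz first so the band labels keep their frequency meaning.
#' @param levels Decomposition depth (default 10).
#' @param drop_details Indices of detail bands to zero (default `c(1, 2)`).
#' @param drop_approx Zero the approximation band? Default `TRUE`.
#' @return A denoised [ecg_signal()] of the same length and rate.
#' @examples
#' sig <- gen_sine(0.2, 400, duration_s = 8, fs = 500)
#' den <- wavelet_denoise(sig)
#' @export
wavelet_denoise <- function(sig, levels = 10L, drop_details = c(1L, 2L),
                            drop_approx = TRUE) {
  dec <- dwt_decompose(sig, levels = levels)
  keep_d <- setdiff(seq_len(dec$levels), as.integer(drop_details))
  keep <- paste0("D", keep_d)
  if (!drop_approx) keep <- c(keep, paste0("A", dec$levels))
  dwt_reconstruct(dec, keep = keep)
}
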