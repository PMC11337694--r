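# shared helpers for the suite: tiny independent oracles and fixtures

# sort a point matrix lexicographically (set comparison of orbits)
sort_points <- function(m) {
  m <- unname(as.matrix(m))
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

# max nearest-neighbour distance from each point of a to the set b (2-D)
max_nn_dist <- function(a, b) {
  max(vapply(seq_len(nrow(a)), function(i) {
    min(sqrt((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2))
  }, numeric(1)))
}

# total energy of a signal
energy <- function(sig) sum(sig$samples^2)

# pure-sine ecg_signal at arbitrary frequency (Hz), for band sweeps
sine_hz <- function(f, duration_s = 8, fs = 500, A = 1) {
  tt <- (seq_len(round(duration_s * fs)) - 1) / fs
  ecg_signal(A * sin(2 * pi * f * tt), fs = fs)
}

# fiducials at fixed period for ideal periodic signals
periodic_fiducials <- function(period_samples, n_samples, fs = 500) {
  as_fiducials(data.frame(r = seq(1, n_samples, by = period_samples)),
               fs = fs, n_samples = n_samples)
}
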