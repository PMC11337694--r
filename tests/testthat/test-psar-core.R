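test_that("tau follows the one-third rule with round-half-away-from-zero", {
  expect_identical(compute_tau(900L), 300L)
  expect_identical(compute_tau(400L), 133L)
  expect_identical(compute_tau(c(3L, 9L, 500L)), c(1L, 3L, 167L))
  expect_error(compute_tau(2L), class = "psar_error_split")
})

test_that("split schemes produce the documented segment boundaries", {
  ecg <- gen_synthetic_ecg(bpm = 60, duration_s = 10, seed = 1)
  fid <- detect_fiducials(ecg$signal)
  rr <- split_cycles(fid, "rr")
  expect_identical(nrow(rr), 9L)
  expect_identical(rr$start, fid$r[-10])
  expect_identical(rr$end, fid$r[-1])
  # consecutive RR segments are contiguous
  expect_identical(rr$end[-9], rr$start[-1])
  qrs <- split_cycles(fid, "qrs")
  expect_identical(nrow(qrs), 10L)
  expect_identical(qrs$start, fid$q)
  expect_identical(qrs$end, fid$s)
  stpq <- split_cycles(fid, "stpq")
  expect_identical(nrow(stpq), 9L)
  expect_identical(stpq$start, fid$s[-10])
  expect_identical(stpq$end, fid$q[-1])
})

test_that("a two-beat record gives one RR segment; fewer beats give none", {
  fid <- as_fiducials(data.frame(r = c(1L, 501L)), fs = 500, n_samples = 1000)
  seg <- split_cycles(fid, "rr")
  expect_identical(nrow(seg), 1L)
  expect_identical(seg$period_samples, 500L)
  one <- as_fiducials(data.frame(r = 100L), fs = 500, n_samples = 1000)
  expect_identical(nrow(split_cycles(one, "rr")), 0L)
})

test_that("constant segments embed to the diagonal point", {
  sig <- ecg_signal(rep(0.7, 300), 500)
  tr <- embed_segment(sig, list(start = 1L, end = 301L, tau_samples = 100L))
  expect_identical(nrow(tr), 300L)
  expect_true(all(tr$x == 0.7 & tr$y == 0.7 & tr$z == 0.7))
})

test_that("a T = 3*tau sine cycle is exactly invariant under cyclic permutation", {
  # brute-force oracle: permuting (x,y,z) -> (y,z,x) must reproduce the same
  # point set, exactly, because the wrapped delay is exactly T/3
  sig <- gen_sine(0.2, 300, duration_s = 0.6, fs = 500)  # one cycle, 300 samples
  tr <- embed_segment(sig, list(start = 1L, end = 301L, tau_samples = 100L))
  a <- sort_points(tr[, c("x", "y", "z")])
  b <- sort_points(cbind(tr$y, tr$z, tr$x))
  expect_identical(a, b)
  expect_equal(max_nn_dist(a[, 1:2], b[, 1:2]), 0)
})

test_that("full-period delays collapse the orbit onto x = y = z", {
  sig <- gen_sine(0.2, 300, duration_s = 0.6, fs = 500)
  for (tau in c(300L, 600L)) {
    tr <- embed_segment(sig, list(start = 1L, end = 301L), tau_override = tau)
    expect_identical(tr$x, tr$y)
    expect_identical(tr$x, tr$z)
  }
})

test_that("truncated mode drops the wrapped tail or empties out", {
  sig <- ecg_signal(rnorm(400), 500)
  seg <- list(start = 1L, end = 401L, tau_samples = 133L)
  tr <- embed_segment(sig, seg, mode = "truncated")
  expect_identical(nrow(tr), 400L - 266L)
  expect_identical(tr$y, sig$samples[134:267])
  expect_warning(
    empty <- embed_segment(sig, list(start = 1L, end = 41L, tau_samples = 20L),
                           mode = "truncated"),
    "empty trajectory")
  expect_identical(nrow(empty), 0L)
})

test_that("the re-spliced attractor preserves point counts and per-cycle tau", {
  ecg <- gen_synthetic_ecg(bpm = 60, rr_cv = 0.1, duration_s = 20, seed = 4)
  fid <- detect_fiducials(ecg$signal)
  traj <- reconstruct_attractor(ecg$signal, fid, "rr")
  segs <- attr(traj, "segments")
  expect_identical(nrow(traj), sum(segs$period_samples))
  expect_identical(segs$tau_samples, compute_tau(segs$period_samples))
  expect_true(!is.unsorted(traj$cycle_id))
})

test_that("strictly periodic input yields identical per-cycle orbits", {
  sig <- gen_sine(0.2, 400, duration_s = 8, fs = 500)  # 800 ms period
  fid <- periodic_fiducials(400L, 4000L)
  traj <- reconstruct_attractor(sig, fid, "rr")
  orbits <- split(as.data.frame(traj[, c("x", "y", "z")]), traj$cycle_id)
  ref <- as.matrix(orbits[[1]])
  for (o in orbits[-1]) {
    expect_lt(max(abs(as.matrix(o) - ref)), 1e-9)
  }
})

test_that("alternating 800/1200 ms cycles give alternating tau 133/200", {
  # the mixed-period signal structure: segment boundaries at 0, 800, 2000,
  # 2800, 4000 ... ms
  sig <- gen_mixed_sine(duration_s = 20, fs = 500)
  bounds_ms <- c(outer(c(0, 800), seq(0, 18000, by = 2000), "+"))
  fid <- as_fiducials(data.frame(r = as.integer(round(bounds_ms / 2)) + 1L),
                      fs = 500, n_samples = 10000)
  segs <- split_cycles(fid, "rr")
  expect_identical(unique(segs$period_samples), c(400L, 600L))
  expect_identical(unique(segs$tau_samples), c(133L, 200L))
})

test_that("segment processing order does not matter", {
  ecg <- gen_synthetic_ecg(bpm = 70, rr_cv = 0.1, duration_s = 15, seed = 8)
  fid <- detect_fiducials(ecg$signal)
  segs <- split_cycles(validate_beats(fid, "rr"), "rr")
  fwd <- lapply(seq_len(nrow(segs)), function(i)
    embed_segment(ecg$signal, segs[i, ], cycle_id = segs$cycle_id[i]))
  rev_ <- lapply(rev(seq_len(nrow(segs))), function(i)
    embed_segment(ecg$signal, segs[i, ], cycle_id = segs$cycle_id[i]))
  a <- dplyr::bind_rows(fwd)
  b <- dplyr::arrange(dplyr::bind_rows(rev_), cycle_id)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("time-rescaled segments trace the same projected point set", {
  # integer-factor resampling with tau scaled by the same factor
  sig1 <- gen_sine(0.2, 300, duration_s = 0.6, fs = 500)
  sig3 <- resample_signal(sig1, 1500)
  p1 <- project_points(embed_segment(sig1, list(start = 1L, end = 301L,
                                                tau_samples = 100L)))
  p3 <- project_points(embed_segment(sig3, list(start = 1L, end = 901L,
                                                tau_samples = 300L)))
  d <- max_nn_dist(cbind(p1$u, p1$v), cbind(p3$u, p3$v))
  expect_lt(d, 0.01 * 0.2)  # < 1 % of amplitude
})
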