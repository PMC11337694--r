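test_that("the ideal sinusoid matches its closed form", {
  sig <- gen_sine(0.2, 400, duration_s = 2, fs = 500)
  # peak of 0.2 sin(pi x / 400) at x = 200 ms
  expect_equal(sig$samples[round(0.2 * 500) + 1], 0.2, tolerance = 1e-12)
  # zero crossings at 0, 400, 800 ms
  for (x_ms in c(0, 400, 800)) {
    expect_lt(abs(sig$samples[round(x_ms / 2) + 1]), 1e-12)
  }
  expect_true(all(gen_sine(0, 400, 1, 500)$samples == 0))
})

test_that("the mixed sinusoid has the stated piecewise structure and period", {
  sig <- gen_mixed_sine()  # A1=0.1, A2=0.4, d1=800, d2=1200
  # first piece peaks at 0.1 at x = 200 ms
  expect_equal(sig$samples[round(0.2 * 500) + 1], 0.1, tolerance = 1e-12)
  # composite 2000 ms periodicity
  n_per <- 1000L
  s <- sig$samples
  expect_lt(max(abs(s[1:(length(s) - n_per)] - s[(n_per + 1):length(s)])), 1e-12)
  # equal-amplitude variant: second piece also peaks at 0.1
  eq <- gen_mixed_sine(A1 = 0.1, A2 = 0.1)
  # second piece peak at x = 800 + 300 = 1100 ms
  expect_equal(eq$samples[round(1.1 * 500) + 1], 0.1, tolerance = 1e-12)
})

test_that("drift injection is exact", {
  base <- gen_sine(0.2, 400, duration_s = 4, fs = 500)
  cst <- add_drift(base, "constant", 0.1)
  expect_equal(cst$samples - base$samples, rep(0.1, 2000))
  lin <- add_drift(base, "linear", 5e-05)
  # sample at t = 2000 ms is raised by exactly 0.1
  k <- round(2 * 500) + 1
  expect_equal(lin$samples[k] - base$samples[k], 0.1, tolerance = 1e-12)
  expect_identical(add_drift(base, "constant", 0)$samples, base$samples)
})

test_that("noise injection is seeded and hits a requested SNR", {
  base <- gen_sine(0.2, 400, duration_s = 20, fs = 500)
  a <- add_noise(base, snr_db = 20, seed = 5)
  b <- add_noise(base, snr_db = 20, seed = 5)
  expect_identical(a$samples, b$samples)
  snr <- 10 * log10(sum(base$samples^2) / sum((a$samples - base$samples)^2))
  expect_lt(abs(snr - 20), 0.5)
  expect_identical(add_noise(base, white_sd = 0)$samples, base$samples)
})

test_that("the PQRST generator produces the requested rhythm", {
  ecg <- gen_synthetic_ecg(bpm = 60, rr_cv = 0, duration_s = 10, seed = 1)
  expect_identical(nrow(ecg$truth), 10L)
  expect_true(all(ecg$rr_ms == 1000))
  # R amplitude 1 mV dominates the noiseless trace
  expect_gte(max(abs(ecg$signal$samples)), 0.95)
  expect_lte(max(abs(ecg$signal$samples)), 1.05)
  # fiducial ordering invariant
  with(ecg$truth, expect_true(all(p < q & q < r & r < s & s < t)))
})

test_that("RR variability matches the requested coefficient of variation", {
  ecg <- gen_synthetic_ecg(bpm = 60, rr_cv = 0.15, duration_s = 510,
                           fs = 100, seed = 21)
  expect_gt(length(ecg$rr_ms), 400)
  cv <- sd(ecg$rr_ms) / mean(ecg$rr_ms)
  expect_lt(abs(cv - 0.15), 0.03)
})

test_that("generators are pure functions of spec and seed", {
  a <- gen_synthetic_ecg(bpm = 72, rr_cv = 0.1, duration_s = 15, seed = 33,
                         noise = list(snr_db = 25))
  b <- gen_synthetic_ecg(bpm = 72, rr_cv = 0.1, duration_s = 15, seed = 33,
                         noise = list(snr_db = 25))
  expect_identical(a$signal$samples, b$signal$samples)
  expect_identical(a$truth$r, b$truth$r)
})

test_that("overlapping wave layouts are rejected", {
  expect_error(gen_synthetic_ecg(bpm = 120, duration_s = 10),
               class = "psar_error_synth")
})
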