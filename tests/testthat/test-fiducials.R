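test_that("R peaks of a clean regular rhythm are found exactly", {
  ecg <- gen_synthetic_ecg(bpm = 60, duration_s = 10, seed = 1)
  pk <- detect_r_peaks(ecg$signal)
  expect_length(pk, 10L)
  expect_lte(max(abs(pk - ecg$truth$r)) / 500 * 1000, 20)
})

test_that("an all-zero signal yields no peaks and empty fiducials", {
  z <- ecg_signal(rep(0, 5000), 500)
  expect_length(detect_r_peaks(z), 0L)
  fid <- refine_fiducials(z, integer(0))
  expect_identical(nrow(fid), 0L)
})

test_that("detection is invariant to positive amplitude rescaling", {
  ecg <- gen_synthetic_ecg(bpm = 75, rr_cv = 0.1, duration_s = 30, seed = 3,
                           noise = list(snr_db = 25))
  pk <- detect_r_peaks(ecg$signal)
  for (k in c(0.2, 7.3)) {
    scaled <- ecg_signal(ecg$signal$samples * k, 500)
    expect_identical(detect_r_peaks(scaled), pk)
  }
})

test_that("waves are localized within physiological tolerances on clean beats", {
  ecg <- gen_synthetic_ecg(bpm = 60, duration_s = 30, seed = 5)
  fid <- detect_fiducials(ecg$signal)
  tr <- ecg$truth
  expect_identical(nrow(fid), nrow(tr))
  ms_err <- function(a, b) abs(a - b) / 500 * 1000
  expect_true(all(ms_err(fid$q, tr$q) <= 25))
  expect_true(all(ms_err(fid$s, tr$s) <= 25))
  expect_true(all(ms_err(fid$p, tr$p) <= 40))
  expect_true(all(ms_err(fid$t, tr$t) <= 40))
})

test_that("a flat P region is reported missing", {
  w <- psar::default_waves()
  w$amp_mv[w$wave == "p"] <- 0
  ecg <- gen_synthetic_ecg(bpm = 60, duration_s = 10, waves = w, seed = 6)
  fid <- detect_fiducials(ecg$signal)
  expect_true(all(is.na(fid$p)))
})

test_that("emitted beats always satisfy P < Q < R < S < T", {
  for (seed in c(2, 8, 14)) {
    ecg <- gen_synthetic_ecg(bpm = 70, rr_cv = 0.12, duration_s = 60,
                             seed = seed, noise = list(snr_db = 20))
    fid <- detect_fiducials(preprocess_pipeline(ecg$signal))
    ok <- function(a, b) all(is.na(a) | is.na(b) | a < b)
    expect_true(ok(fid$p, fid$q) && ok(fid$q, fid$r) &&
                ok(fid$r, fid$s) && ok(fid$s, fid$t))
  }
})

test_that("validate_beats applies the per-method wave requirements", {
  ecg <- gen_synthetic_ecg(bpm = 60, duration_s = 12, seed = 9)
  fid <- detect_fiducials(ecg$signal)
  expect_identical(nrow(validate_beats(fid, "qrs")), nrow(fid))
  # knock out one S wave: that beat is dropped for QRS, kept for RR
  fid2 <- fid
  fid2$s[3] <- NA_integer_
  expect_message(v <- validate_beats(fid2, "qrs"), "dropped 1")
  expect_identical(nrow(v), nrow(fid) - 1L)
  expect_identical(nrow(validate_beats(fid2, "rr")), nrow(fid))
  # RR never drops beats for missing P/T
  fid3 <- fid
  fid3$p <- NA_integer_
  fid3$t <- NA_integer_
  expect_identical(nrow(validate_beats(fid3, "rr")), nrow(fid))
})

test_that("drift plus preprocessing leaves R indices essentially unchanged", {
  ecg <- gen_synthetic_ecg(bpm = 65, rr_cv = 0.08, duration_s = 30, seed = 12)
  pk_ref <- detect_r_peaks(preprocess_pipeline(ecg$signal))
  drifted <- add_drift(ecg$signal, "linear", 5e-05)
  pk_drift <- detect_r_peaks(preprocess_pipeline(drifted))
  expect_identical(length(pk_ref), length(pk_drift))
  expect_lte(max(abs(pk_ref - pk_drift)), 1)
})

test_that("RR series is recovered accurately across seeds", {
  # scaled-down standing check (10 seeds x 60 s); the full 50 x 120 s run
  # backs the acceptance suite
  errs <- c()
  for (seed in 1:10) {
    ecg <- gen_synthetic_ecg(bpm = 70, rr_cv = 0.15, duration_s = 60,
                             seed = seed, noise = list(snr_db = 20))
    pk <- detect_r_peaks(preprocess_pipeline(ecg$signal))
    m <- match_events(pk, ecg$truth$r, 500)
    expect_gte(m$sensitivity, 0.99)
    expect_gte(m$precision, 0.99)
    rr_det <- diff(pk) / 500 * 1000
    if (length(rr_det) == length(ecg$rr_ms)) {
      errs <- c(errs, mean(abs(rr_det - ecg$rr_ms)))
    }
  }
  expect_gt(length(errs), 5)
  expect_lt(mean(errs), 10)
})
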