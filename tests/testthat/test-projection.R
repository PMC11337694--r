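test_that("the projection basis is orthonormal", {
  withr::with_seed(2, {
    m <- matrix(rnorm(300), ncol = 3)
  })
  tr <- tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3], cycle_id = 1L)
  p <- project_points(tr)
  expect_lt(max(abs(p$u^2 + p$v^2 + p$w^2 - rowSums(m^2))), 1e-10)
  expect_lt(max(abs(p$w - rowSums(m) / sqrt(3))), 1e-12)
})

test_that("diagonal points project to the in-plane origin", {
  tr <- tibble::tibble(x = c(-3, 0, 0.7), y = c(-3, 0, 0.7),
                       z = c(-3, 0, 0.7), cycle_id = 1L)
  p <- project_points(tr)
  expect_true(all(p$u == 0 & p$v == 0))
})

test_that("a constant signal offset moves only the w coordinate", {
  sig <- gen_sine(0.2, 400, duration_s = 8, fs = 500)
  fid <- periodic_fiducials(400L, 4000L)
  p0 <- project_points(reconstruct_attractor(sig, fid, "rr"))
  p1 <- project_points(reconstruct_attractor(
    add_drift(sig, "constant", 0.1), fid, "rr"))
  expect_lt(max(abs(p0$u - p1$u)), 1e-12)
  expect_lt(max(abs(p0$v - p1$v)), 1e-12)
  expect_equal(p1$w - p0$w, rep(0.1 * sqrt(3), nrow(p0)), tolerance = 1e-9)
})

test_that("density maps count in-range points and honour edges", {
  pts <- tibble::tibble(u = c(0, 0.5, -0.5, 1, 2), v = c(0, 0.5, -0.5, 1, 0),
                        w = 0, cycle_id = 1L)
  dm <- make_density_map(pts, rows = 5, cols = 5,
                         u_range = c(-1, 1), v_range = c(-1, 1))
  # the point at u = 2 is clipped; u = v = 1 falls in the top-edge bin
  expect_identical(dm$n_points_in, 4L)
  expect_identical(dm$n_points_clipped, 1L)
  expect_identical(sum(dm$grid), 4L)
  expect_identical(dm$grid[5, 5], 1L)
  # single point at the origin of an odd grid sits in the centre bin
  one <- make_density_map(tibble::tibble(u = 0, v = 0, w = 0, cycle_id = 1L),
                          rows = 5, cols = 5,
                          u_range = c(-1, 1), v_range = c(-1, 1))
  expect_identical(which(one$grid > 0), 13L)
  # empty input with explicit ranges gives an all-zero map
  zero <- make_density_map(tibble::tibble(u = double(0), v = double(0),
                                          w = double(0), cycle_id = integer(0)),
                           rows = 4, cols = 4,
                           u_range = c(-1, 1), v_range = c(-1, 1))
  expect_true(all(zero$grid == 0))
})

test_that("normalization scales to unit maximum and log mode is monotone", {
  withr::with_seed(7, {
    pts <- tibble::tibble(u = runif(500, -1, 1), v = runif(500, -1, 1),
                          w = 0, cycle_id = 1L)
  })
  dm <- make_density_map(pts, rows = 16, cols = 16,
                         u_range = c(-1, 1), v_range = c(-1, 1))
  lin <- normalize_density(dm, "linear")
  expect_equal(max(lin$grid), 1)
  lg <- normalize_density(dm, "log")
  expect_equal(max(lg$grid), 1)
  o1 <- order(as.vector(dm$grid))
  expect_identical(order(as.vector(lg$grid)[o1]), seq_along(o1))
  # all-zero maps pass through untouched
  z <- make_density_map(tibble::tibble(u = double(0), v = double(0),
                                       w = double(0), cycle_id = integer(0)),
                        rows = 3, cols = 3, u_range = c(-1, 1),
                        v_range = c(-1, 1))
  zn <- normalize_density(z, "linear")
  expect_true(all(zn$grid == 0) && !any(is.nan(zn$grid)))
})

test_that("rendered PNGs are deterministic and well-formed", {
  ecg <- gen_synthetic_ecg(bpm = 60, duration_s = 10, seed = 1)
  fid <- detect_fiducials(ecg$signal)
  dm <- make_density_map(project_points(
    reconstruct_attractor(ecg$signal, fid, "rr")))
  p1 <- file.path(tempdir(), "dm1.png")
  p2 <- file.path(tempdir(), "dm2.png")
  render_image(dm, p1)
  render_image(dm, p2)
  b1 <- readBin(p1, "raw", file.info(p1)$size)
  expect_identical(b1, readBin(p2, "raw", file.info(p2)$size))
  # PNG signature and IHDR dimensions (224 x 224)
  expect_identical(as.integer(b1[1:8]), c(137L, 80L, 78L, 71L, 13L, 10L, 26L, 10L))
  dims <- function(off) sum(as.integer(b1[off:(off + 3)]) * 256^(3:0))
  expect_identical(dims(17), 224)  # width
  expect_identical(dims(21), 224)  # height
})

test_that("an independent PNG reader reproduces the rendered pixels", {
  # cross-check the hand-rolled writer against Pillow
  dm <- make_density_map(tibble::tibble(u = c(-0.5, 0, 0.5), v = c(0, 0.5, -0.25),
                                        w = 0, cycle_id = 1L),
                         rows = 8, cols = 8, u_range = c(-1, 1),
                         v_range = c(-1, 1))
  path <- file.path(tempdir(), "oracle.png")
  render_image(normalize_density(dm, "linear"), path)
  script <- sprintf(
    "from PIL import Image; import sys; im = Image.open(r'%s'); a = list(im.getdata()); print(im.size[0], im.size[1], im.mode, sum(1 for v in a if v > 0), max(a))",
    path)
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  parts <- strsplit(out, " ")[[1]]
  expect_identical(parts[1:3], c("8", "8", "L"))
  expect_identical(as.integer(parts[4]), occupied_bins(dm))
  expect_identical(as.integer(parts[5]), 255L)
})

test_that("Z3-symmetric orbits give 120-degree rotation-invariant maps", {
  # cyclic coordinate permutation = 120 deg rotation about the grid centre;
  # compare binned mass overlap to allow discretization error
  sig <- gen_sine(0.2, 300, duration_s = 0.6, fs = 500)
  tr <- embed_segment(sig, list(start = 1L, end = 301L, tau_samples = 100L))
  rot <- tibble::tibble(x = tr$y, y = tr$z, z = tr$x, cycle_id = tr$cycle_id)
  r <- c(-0.3, 0.3)
  d0 <- make_density_map(project_points(tr), u_range = r, v_range = r,
                         upsample = 4)
  d1 <- make_density_map(project_points(rot), u_range = r, v_range = r,
                         upsample = 4)
  overlap <- sum(pmin(d0$grid, d1$grid)) / sum(d0$grid)
  expect_gte(overlap, 0.95)
})

test_that("trajectory upsampling densifies the traced curve", {
  sig <- gen_sine(0.2, 400, duration_s = 8, fs = 500)
  fid <- periodic_fiducials(400L, 4000L)
  p <- project_points(reconstruct_attractor(sig, fid, "rr"))
  r <- c(-0.3, 0.3)
  o1 <- occupied_bins(make_density_map(p, u_range = r, v_range = r))
  o8 <- occupied_bins(make_density_map(p, u_range = r, v_range = r,
                                       upsample = 8))
  expect_gt(o8, o1)
})
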