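test_that("minimum-norm kernel matches an independent naive formula", {
  set.seed(17)
  g <- matrix(rnorm(5 * 8), 5, 8)
  lf <- list(gain = g, sensor_names = sprintf("S%d", 1:5))
  inv <- make_inverse(lf, snr = 3)
  # independent oracle: direct formula evaluation
  lambda <- sum(diag(g %*% t(g))) / (5 * 9)
  kern <- t(g) %*% solve(g %*% t(g) + lambda * diag(5))
  expect_lt(max(abs(inv$kernel - kern)), 1e-8)
  std <- 1 / sqrt(diag(kern %*% g))
  expect_lt(max(abs(inv$kernel_std - kern * std)), 1e-8)
})

test_that("lambda -> 0 with a square invertible leadfield recovers the inverse", {
  set.seed(18)
  g <- matrix(rnorm(16), 4, 4) + 4 * diag(4)
  lf <- list(gain = g, sensor_names = sprintf("S%d", 1:4))
  inv <- make_inverse(lf, snr = 1e6)
  expect_equal(inv$kernel, solve(g), tolerance = 1e-6)
})

test_that("standardized estimate peaks at the true source (zero localisation error)", {
  cfg <- toy_config(seed = 12)
  lf <- make_leadfield(cfg)
  inv <- make_inverse(lf, snr = 30)
  hits <- vapply(seq_len(ncol(lf$gain)), function(s)
    which.max(abs(inv$kernel_std %*% lf$gain[, s])) == s, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("peak standardized score is location-independent on a symmetric sphere", {
  sens <- eegnorm:::fibonacci_sphere(64)
  srcp <- eegnorm:::fibonacci_sphere(96) * 0.5
  ori <- eegnorm:::unit_rows(srcp)
  g <- eegnorm:::sphere_gain(sens, srcp, ori)
  lf <- list(gain = g, sensor_names = sprintf("S%02d", 1:64))
  inv <- make_inverse(lf, snr = 30)
  peaks <- vapply(1:96, function(s) max(abs(inv$kernel_std %*% g[, s])), 0)
  expect_lt(sd(peaks) / mean(peaks), 0.10)
  # the unstandardized minimum norm does not have this property
  raw <- vapply(1:96, function(s) max(abs(inv$kernel %*% g[, s])), 0)
  expect_gt(sd(raw) / mean(raw), sd(peaks) / mean(peaks))
})

test_that("apply_inverse is linear and channel-checked", {
  cfg <- toy_config(seed = 13)
  lf <- make_leadfield(cfg)
  inv <- make_inverse(lf)
  n <- 500
  mk <- function(d) sensor_recording(d, 250, channel_names = lf$sensor_names)
  x <- matrix(rnorm(cfg$n_sensors * n), cfg$n_sensors)
  y <- matrix(rnorm(cfg$n_sensors * n), cfg$n_sensors)
  expect_equal(unname(apply_inverse(mk(matrix(0, cfg$n_sensors, n)), inv)$data),
               matrix(0, cfg$n_sources, n))
  expect_equal(apply_inverse(mk(x + y), inv)$data,
               apply_inverse(mk(x), inv)$data + apply_inverse(mk(y), inv)$data,
               tolerance = 1e-12)
  bad <- sensor_recording(x, 250, channel_names = sprintf("Z%d", seq_len(cfg$n_sensors)))
  expect_error(apply_inverse(bad, inv), "lacks operator channels")
})

test_that("sign-flip averaging defeats anti-parallel cancellation", {
  # two sources, identical series, opposite normals
  ori <- rbind(c(0, 0, 1), c(0, 0, -1))
  lf <- list(orientations = ori)
  parc <- structure(list(roi = data.frame(roi_id = 1, roi_name = "r1"),
                         source_roi = c(1L, 1L), n_rois = 1L),
                    class = "parcellation")
  s <- sin(2 * pi * 5 * (0:999) / 250)
  # constrained estimates come out with opposite signs for opposite walls
  src <- structure(list(data = rbind(s, -s), fs = 250), class = "source_estimate")
  out <- roi_average(src, lf, parc)
  expect_equal(abs(out$data[1, ]), abs(s), tolerance = 1e-12)  # +-s, not 0
  # naive unflipped mean would be exactly zero
  expect_equal(max(abs(colMeans(src$data))), 0)
})

test_that("roi averaging matches a brute-force flip-and-mean oracle", {
  set.seed(19)
  m <- 5; n <- 200
  ori <- eegnorm:::unit_rows(matrix(rnorm(m * 3), m))
  lf <- list(orientations = ori)
  parc <- structure(list(roi = data.frame(roi_id = 1, roi_name = "r1"),
                         source_roi = rep(1L, m), n_rois = 1L),
                    class = "parcellation")
  dat <- matrix(rnorm(m * n), m)
  src <- structure(list(data = dat, fs = 100), class = "source_estimate")
  out <- roi_average(src, lf, parc)
  # oracle: principal orientation via svd, explicit per-source loop
  u <- svd(ori)$v[, 1]
  acc <- rep(0, n)
  for (i in 1:m) {
    sg <- sign(sum(ori[i, ] * u)); if (sg == 0) sg <- 1
    acc <- acc + sg * dat[i, ]
  }
  expect_lt(max(abs(out$data[1, ] - acc / m)), 1e-10)
  # globally negating all normals changes at most the overall sign
  lf2 <- list(orientations = -ori)
  out2 <- roi_average(src, lf2, parc)
  expect_true(max(abs(out2$data - out$data)) < 1e-12 ||
                max(abs(out2$data + out$data)) < 1e-12)
})

test_that("single-source ROIs pass through and empty ROIs are named", {
  lf <- list(orientations = matrix(c(0, 0, 1), 1))
  parc <- structure(list(roi = data.frame(roi_id = 1:2,
                                          roi_name = c("solo", "ghost")),
                         source_roi = 1L, n_rois = 2L),
                    class = "parcellation")
  src <- structure(list(data = matrix(rnorm(50), 1), fs = 100),
                   class = "source_estimate")
  expect_error(roi_average(src, lf, parc), "ghost")
  parc$roi <- parc$roi[1, ]; parc$n_rois <- 1L
  out <- roi_average(src, lf, parc)
  expect_true(all(out$data[1, ] == src$data[1, ]) ||
                all(out$data[1, ] == -src$data[1, ]))
})

test_that("the sensor-to-ROI chain is homogeneous of degree one", {
  cfg <- toy_config(seed = 14)
  lf <- make_leadfield(cfg)
  parc <- make_parcellation(cfg)
  inv <- make_inverse(lf)
  x <- matrix(rnorm(cfg$n_sensors * 300), cfg$n_sensors)
  mk <- function(d) sensor_recording(d, 250, channel_names = lf$sensor_names)
  a <- roi_average(apply_inverse(mk(3.7 * x), inv), lf, parc)
  b <- roi_average(apply_inverse(mk(x), inv), lf, parc)
  expect_equal(a$data, 3.7 * b$data, tolerance = 1e-10)
})
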