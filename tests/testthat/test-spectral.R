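test_that("epoch selection slices exactly and validates bounds", {
  ts <- ts_of(matrix(rnorm(2 * 90 * 250), 2), fs = 250)
  ep <- select_epoch(ts, 0, 60)
  expect_equal(ncol(ep$data), 60 * 250)
  expect_equal(ep$data, ts$data[, 1:15000])
  expect_identical(select_epoch(ts, 0, 90)$data, ts$data)
  expect_error(select_epoch(ts, 40, 60), "exceeds")
  # three non-overlapping 30-s epochs tile a 90-s series
  starts <- epoch_plan(90, 30, 3)
  expect_equal(starts, c(0, 30, 60))
  segs <- lapply(starts, function(s) select_epoch(ts, s, 30)$data)
  expect_equal(do.call(cbind, segs), ts$data)
})

test_that("Welch PSD of a unit sine integrates to A^2/2 with 2 s / 50% layout", {
  ts <- ts_of(sine_wave(10), fs = 250)
  sp <- welch_psd(ts, window = 2, overlap = 0.5)
  # 2 s window at 250 Hz -> 500-sample segments, 0.5 Hz resolution
  expect_equal(diff(sp$freqs)[1], 0.5)
  expect_equal(length(sp$freqs), 251)
  tot <- pracma::trapz(sp$freqs, sp$psd[1, ])
  expect_equal(tot, 0.5, tolerance = 0.02)
  expect_true(all(welch_psd(ts_of(rep(0, 5000)))$psd == 0))
  expect_error(welch_psd(ts_of(rnorm(100), fs = 250), window = 2), "shorter")
})

test_that("band integration is half-open with >= 95% of a sine's power in its band", {
  scheme <- band_scheme()
  sp <- welch_psd(ts_of(sine_wave(10)))
  bp <- band_power(sp, scheme)
  expect_gt(bp[1, "alpha"] / sum(bp[1, ]), 0.95)
  # a 4 Hz sine sits on the delta/theta edge: its band is theta, with only
  # spectral leakage reaching delta
  bp4 <- band_power(welch_psd(ts_of(sine_wave(4))), scheme)
  expect_gt(bp4[1, "theta"], 5 * bp4[1, "delta"])
  # crisp half-open check on a synthetic line spectrum: all power exactly at
  # the 4 Hz bin belongs to theta, none to delta
  line <- structure(list(freqs = seq(0, 125, by = 0.5),
                         psd = matrix(as.numeric(seq(0, 125, by = 0.5) == 4),
                                      nrow = 1),
                         roi_names = "line"), class = "spectrum_welch")
  bpl <- band_power(line, scheme)
  expect_equal(unname(bpl[1, "delta"]), 0)
  expect_gt(bpl[1, "theta"], 0)
  # 47.5 Hz (upper edge of the last band) is counted in gamma
  bp47 <- band_power(welch_psd(ts_of(sine_wave(47.5))), scheme)
  expect_equal(unname(which.max(bp47[1, ])), 5L)
})

test_that("white noise band powers scale with bandwidth", {
  set.seed(23)
  ts <- ts_of(rnorm(120 * 250), fs = 250)
  bp <- band_power(welch_psd(ts), band_scheme())
  # effective trapezoid width per band: (n_bins - 1) * df under the
  # half-open convention (last band keeps its upper edge)
  widths <- c(2.5, 3.5, 4.5, 16.5, 17.5)
  ratio <- bp[1, ] / widths
  expect_lt(max(ratio) / min(ratio), 1.15)
})

test_that("relative band power is row-stochastic and scale invariant", {
  set.seed(24)
  ts <- ts_of(matrix(rnorm(3 * 60 * 250), 3), fs = 250)
  m1 <- bandpower_map(ts)
  expect_equal(unname(rowSums(m1$values)), rep(1, 3), tolerance = 1e-9)
  expect_true(all(m1$values >= 0 & m1$values <= 1))
  ts2 <- ts; ts2$data[2, ] <- 17.3 * ts2$data[2, ]
  m2 <- bandpower_map(ts2)
  expect_equal(m2$values[2, ], m1$values[2, ], tolerance = 1e-9)
})

test_that("two equal sines split relative power evenly; degenerate rows error", {
  x <- sine_wave(10) + sine_wave(20)
  m <- bandpower_map(ts_of(x))
  expect_equal(unname(m$values[1, "alpha"]), 0.5, tolerance = 0.02)
  expect_equal(unname(m$values[1, "beta"]), 0.5, tolerance = 0.02)
  ap <- rbind(ok = c(1, 2, 3), dead = c(0, 0, 0))
  expect_error(relative_band_power(ap), "dead")
  # pure alpha concentrates its row
  ap2 <- matrix(c(0, 0, 1, 0, 0), 1,
                dimnames = list("r", c("delta", "theta", "alpha", "beta", "gamma")))
  expect_equal(unname(relative_band_power(ap2)$values[1, ]),
               c(0, 0, 1, 0, 0))
})

test_that("Welch relative power is stable across independent realisations", {
  cfg <- toy_config(seed = 25)
  parc <- make_parcellation(cfg)
  cfg$duration <- 60
  vals <- vapply(1:8, function(i) {
    sim <- simulate_roi_series(cfg, parc, 1000 + i)
    bandpower_map(sim$ts, cfg$scheme, epoch_duration = 60)$values[3, "alpha"]
  }, 0)
  expect_lt(sd(vals), 0.03)
})
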