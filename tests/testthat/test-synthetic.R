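test_that("parcellation has the configured pair/unpaired/temporal structure", {
  p <- make_parcellation(sim_config())
  expect_equal(nrow(p$roi), 114)
  expect_equal(nrow(p$pairs), 54)
  expect_equal(sum(p$roi$hemisphere == "M"), 6)
  expect_equal(sum(p$roi$temporal), 26)
  expect_equal(sum(p$pairs$temporal), 13)
  # partition: every source in exactly one ROI, all ROIs non-empty
  expect_equal(sort(unique(p$source_roi)), p$roi$roi_id)
  expect_equal(length(p$source_roi), 400)
  counts <- tabulate(p$source_roi, nbins = p$n_rois)
  expect_true(all(counts >= 1))
  # homologous pairs mirror exactly in x
  left <- p$roi[p$pairs$roi_left, ]
  right <- p$roi[p$pairs$roi_right, ]
  expect_equal(left$cx, -right$cx)
  expect_equal(left$cy, right$cy)
})

test_that("leadfield construction is seeded-deterministic with sane gains", {
  cfg <- toy_config(seed = 3)
  lf1 <- make_leadfield(cfg)
  lf2 <- make_leadfield(cfg)
  expect_identical(lf1$gain, lf2$gain)
  expect_true(all(colSums(abs(lf1$gain)) > 0))
  expect_equal(qr(lf1$gain)$rank, cfg$n_sensors)  # full row rank
  expect_equal(unname(sqrt(rowSums(lf1$orientations^2))),
               rep(1, cfg$n_sources), tolerance = 1e-12)
  # orientation-linearity: flipping a normal flips the column
  g2 <- lf1
  expect_equal(make_leadfield(cfg, mode = "sphere")$gain[, 1],
               -eegnorm:::sphere_gain(lf1$sensor_positions,
                                      matrix(lf1$source_positions[1, ], 1),
                                      matrix(-lf1$orientations[1, ], 1))[, 1])
})

test_that("centre dipole in the sphere model peaks under the aligned sensor", {
  sens <- eegnorm:::fibonacci_sphere(40)
  # dipole at the centre pointing straight at sensor 17
  target <- sens[17, ]
  g <- eegnorm:::sphere_gain(sens, matrix(0, 1, 3), matrix(target, 1))
  expect_equal(which.max(abs(g[, 1])), 17L)
  # brute-force: potential should be proportional to cos(angle to moment)
  expect_gt(cor(g[, 1], sens %*% target), 0.9999)
})

test_that("subject simulation is seeded-deterministic and dimensioned", {
  cfg <- toy_config()
  parc <- make_parcellation(cfg)
  lf <- make_leadfield(cfg)
  s1 <- simulate_subject(cfg, lf, parc, 42)
  s2 <- simulate_subject(cfg, lf, parc, 42)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_equal(nrow(s1$recording$data), cfg$n_sensors + 1)  # + ECG
  expect_equal(ncol(s1$recording$data), cfg$duration * cfg$fs)
  s3 <- simulate_subject(cfg, lf, parc, 43)
  expect_false(identical(s1$recording$data, s3$recording$data))
})

test_that("dimension mismatches name the offending axis", {
  cfg <- toy_config()
  parc <- make_parcellation(cfg)
  lf <- make_leadfield(cfg)
  lf_bad <- lf
  lf_bad$gain <- lf$gain[, 1:10]
  expect_error(simulate_subject(cfg, lf_bad, parc, 1), "source axis")
  lf_bad2 <- lf
  lf_bad2$gain <- lf$gain[1:5, ]
  expect_error(simulate_subject(cfg, lf_bad2, parc, 1), "sensor axis")
})

test_that("single-ROI alpha profile concentrates the sensor spectrum in 8-13 Hz", {
  cfg <- toy_config(seed = 2)
  cfg$sensor_noise_sd <- 0
  cfg$pink_weight <- 0
  cfg$artifact$enabled <- FALSE
  cfg$subject_sd <- 0
  parc <- make_parcellation(cfg)
  prof <- matrix(1e-12, parc$n_rois, 5,
                 dimnames = list(parc$roi$roi_name, band_names(cfg$scheme)))
  prof[5, "alpha"] <- 1
  cfg$band_profiles <- prof   # other regions essentially silent
  lf <- make_leadfield(cfg)
  s <- simulate_subject(cfg, lf, parc, 11)
  ch <- s$recording$data[which.max(abs(lf$gain[, roi_sources(parc, 5)[1]])), ]
  sp <- welch_psd(ts_of(ch, fs = cfg$fs))
  bp <- band_power(sp, cfg$scheme)
  expect_gt(bp[1, "alpha"] / sum(bp), 0.95)
})

test_that("realized source-space relative band power matches the planted profile", {
  cfg <- toy_config(seed = 4)
  parc <- make_parcellation(cfg)
  sim <- simulate_roi_series(cfg, parc, 123)
  maps <- bandpower_map(sim$ts, cfg$scheme, epoch_duration = cfg$duration,
                        subject_id = "calib")
  expect_true(all(abs(maps$values - sim$planted) < 0.05))
  expect_equal(unname(rowSums(sim$planted)), rep(1, parc$n_rois),
               tolerance = 1e-9)
})

test_that("cohort simulation yields 17 + 22 distinct recordings with planted patient effects", {
  cfg <- toy_config(seed = 5)
  cfg$duration <- 20
  sim <- simulate_cohorts(cfg)
  expect_length(sim$healthy, cfg$n_healthy)
  expect_length(sim$patients, cfg$n_patients)
  expect_true(all(sim$truth$patient_sides %in% c("L", "R")))
  expect_length(sim$truth$patient_sides, cfg$n_patients)
  # distinct subject substreams -> distinct data
  expect_false(identical(sim$healthy[[1]]$recording$data,
                         sim$healthy[[2]]$recording$data))
  # planted effect raises the affected band's planted relative power
  pat <- sim$patients[[1]]$truth
  base <- sim$truth$roi_band_power
  aff <- pat$effect$rois
  expect_true(all(pat$roi_band_power[aff, sim$truth$affected_band] >
                    base[aff, sim$truth$affected_band]))
  # default study-scale cohort counts
  expect_equal(sim_config()$n_healthy, 17)
  expect_equal(sim_config()$n_patients, 22)
})

test_that("effect factor 1 leaves patients exchangeable with controls", {
  cfg <- toy_config(seed = 6)
  cfg$patient_effect$factor <- 1
  parc <- make_parcellation(cfg)
  base <- ground_truth_profile(cfg, parc)
  withf <- ground_truth_profile(cfg, parc,
                                effect = list(rois = c(1, 2), band = "delta",
                                              factor = 1))
  expect_equal(base, withf)
})

test_that("fast band-power cohorts are row-stochastic and centred on the planted profile", {
  cfg <- toy_config(seed = 8)
  parc <- make_parcellation(cfg)
  maps <- simulate_bandpower_cohort(cfg, 200, parcellation = parc, seed = 21)
  expect_length(maps, 200)
  expect_true(all(vapply(maps, function(m)
    max(abs(rowSums(m) - 1)) < 1e-9, TRUE)))
  mu <- Reduce(`+`, maps) / length(maps)
  expect_true(max(abs(mu - ground_truth_profile(cfg, parc))) < 0.02)
})

test_that("parcellation TSV round-trips", {
  p <- make_parcellation(toy_config())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_parcellation(p, path)
  p2 <- read_parcellation(path)
  expect_equal(p2$roi$roi_name, p$roi$roi_name)
  expect_equal(p2$source_roi, p$source_roi)
  expect_equal(p2$pairs$roi_left, p$pairs$roi_left)
})
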