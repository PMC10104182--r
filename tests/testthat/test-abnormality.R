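test_that("z-scoring against the normative map follows the defining formula", {
  mu <- matrix(0.2, 3, 5,
               dimnames = list(c("r1", "r2", "r3"),
                               c("delta", "theta", "alpha", "beta", "gamma")))
  norm <- list(mu = mu, sigma = mu * 0 + 0.05, n_subjects = 17)
  # x = mu -> all zeros
  z0 <- zscore_map(mu, norm)
  expect_true(all(z0$z == 0))
  expect_true(all(z0$max_abs_z == 0))
  # x = mu + 2 sigma at one cell -> z = 2 there
  x <- mu; x[2, 3] <- mu[2, 3] + 2 * 0.05
  z2 <- zscore_map(x, norm)
  expect_equal(z2$z[2, 3], 2)
  expect_equal(unname(z2$max_abs_z["r2"]), 2)
  # hand arithmetic: (0.30 - 0.20) / 0.05 = 2
  x2 <- mu; x2[1, 1] <- 0.30
  expect_equal(zscore_map(x2, norm)$z[1, 1], 2)
  # zero sigma errors with the cell named
  norm_bad <- norm; norm_bad$sigma[3, 2] <- 0
  expect_error(zscore_map(mu, norm_bad), "'r3'.*'theta'")
  # max_abs_z is exactly the row max of |z|
  set.seed(51)
  xr <- mu + matrix(rnorm(15, sd = 0.1), 3)
  zr <- zscore_map(xr, norm)
  expect_equal(zr$max_abs_z, apply(abs(zr$z), 1, max))
})

test_that("z-scores are invariant under consistent ROI reordering", {
  set.seed(52)
  mu <- matrix(runif(20, 0.1, 0.3), 4, 5,
               dimnames = list(sprintf("r%d", 1:4), NULL))
  norm <- list(mu = mu, sigma = mu * 0.2, n_subjects = 10)
  x <- mu + matrix(rnorm(20, sd = 0.02), 4)
  perm <- c(3, 1, 4, 2)
  norm_p <- list(mu = mu[perm, ], sigma = norm$sigma[perm, ], n_subjects = 10)
  expect_equal(zscore_map(x[perm, ], norm_p)$z, zscore_map(x, norm)$z[perm, ])
})

test_that("temporal restriction keeps 26 ROIs in 13 pairs", {
  parc <- make_parcellation(sim_config())
  norm <- list(mu = matrix(0.2, 114, 5), sigma = matrix(0.05, 114, 5))
  z <- zscore_map(matrix(0.2, 114, 5), norm)
  zt <- restrict_temporal(z, parc)
  expect_equal(nrow(zt$z), 26)
  expect_equal(length(unique(parc$roi$pair_id[zt$roi_ids])), 13)
  expect_true(all(parc$roi$temporal[zt$roi_ids]))
})

test_that("paired lateralisation statistics match the closed form", {
  # three patients engineered so that ipsi - contra = 1, 2, 3 on pair 1
  parc <- structure(list(
    roi = data.frame(roi_id = 1:2, roi_name = c("tl", "tr"),
                     hemisphere = c("L", "R"), temporal = TRUE,
                     pair_id = 1),
    pairs = data.frame(pair_id = 1, roi_left = 1, roi_right = 2,
                       temporal = TRUE, anteriority = 0),
    n_rois = 2L), class = "parcellation")
  mk <- function(l, r) list(max_abs_z = c(l, r), z = NULL)
  cohort <- list(mk(2, 1), mk(3, 1), mk(4, 1))
  lat <- lateralize(cohort, c("L", "L", "L"), parc)
  expect_equal(lat$table$mean_diff, 2)
  expect_equal(lat$table$sd_diff, 1)
  expect_equal(lat$table$d_z, 2)
  expect_equal(lat$table$t, 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(lat$table$t, lat$table$d_z * sqrt(lat$table$n), tolerance = 1e-9)
  # ipsi == contra everywhere -> zero-variance flagged as NA, mean diff 0
  cohort0 <- list(mk(1, 1), mk(1, 1), mk(1, 1))
  lat0 <- lateralize(cohort0, c("L", "R", "L"), parc)
  expect_equal(lat0$table$mean_diff, 0)
  expect_true(is.na(lat0$table$d_z) && is.na(lat0$table$t))
  expect_error(lateralize(cohort, c("L", "L"), parc), "sides length")
  expect_error(lateralize(cohort, c("L", "L", "X"), parc), "'L' or 'R'")
})

test_that("flipping every lateralisation label negates t exactly", {
  cfg <- sim_config(seed = 61)
  parc <- make_parcellation(cfg)
  maps <- simulate_bandpower_cohort(cfg, 30, parcellation = parc, seed = 62)
  norm <- build_normative_map(maps[1:8])
  cohort <- lapply(maps[9:30], function(m) zscore_map(m, norm))
  sides <- rep(c("L", "R"), 11)
  lat1 <- lateralize(cohort, sides, parc)
  lat2 <- lateralize(cohort, ifelse(sides == "L", "R", "L"), parc)
  expect_equal(lat2$table$t, -lat1$table$t)
  expect_equal(lat2$table$d_z, -lat1$table$d_z)
  expect_equal(lat2$table$mean_ipsi, lat1$table$mean_contra)
})

test_that("cohort statistics reproduce the chi-square oracle and pooled t", {
  controls <- list(n = 17, age_mean = 31.9, age_sd = 6.46, sex_m = 11, sex_f = 6)
  patients <- list(n = 22, age_mean = 34.2, age_sd = 10.1, sex_m = 9,
                   sex_f = 13, lat_l = 14, lat_r = 8)
  ct <- cohort_stats(controls, patients)
  # brute-force Pearson chi-square: sum (O - E)^2 / E
  o <- matrix(c(11, 6, 9, 13), 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  expect_equal(ct$sex$chisq, sum((o - e)^2 / e), tolerance = 1e-12)
  expect_equal(ct$sex$chisq, 2.17, tolerance = 0.01)
  # pooled two-sample t from summary statistics
  sp2 <- (16 * 6.46^2 + 21 * 10.1^2) / 37
  expect_equal(ct$age$t, (31.9 - 34.2) / sqrt(sp2 * (1 / 17 + 1 / 22)),
               tolerance = 1e-12)
  expect_lt(abs(ct$age$p - 0.41), 0.01)
  expect_equal(ct$age$pooled_sd, 8.71, tolerance = 0.001)
  expect_equal(ct$lateralisation, c(L = 14, R = 8))
  # perfectly proportional table -> chi-square 0
  ct0 <- cohort_stats(list(n = 20, age_mean = 30, age_sd = 5, sex_m = 10, sex_f = 10),
                      list(n = 40, age_mean = 30, age_sd = 5, sex_m = 20, sex_f = 20))
  expect_equal(ct0$sex$chisq, 0)
  expect_error(cohort_stats(list(n = 5, age_mean = 1, age_sd = 1, sex_m = 5, sex_f = 0),
                            list(n = 5, age_mean = 1, age_sd = 1, sex_m = 5, sex_f = 0)),
               "empty")
})
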