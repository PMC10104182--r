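# Source-signal synthesis. Each region carries a sum of band-limited
# Gaussian noise components (one per frequency band, planted power p_ij)
# plus a 1/f background. Band components are synthesized in the frequency
# domain by shaping white-noise spectra with the squared magnitude response
# of an order-4 Butterworth band-pass (the zero-phase response a
# forward-backward filter would impose), which makes the planted per-band
# power exactly computable from the realized shaping functions.

# zero-phase (two-pass) Butterworth band-pass amplitude response
butter_bp_shape <- function(f, fmin, fmax, order = 4) {
  f0sq <- fmin * fmax
  bw <- fmax - fmin
  w <- ifelse(f <= 0, Inf, (f^2 - f0sq) / (f * bw))
  1 / (1 + w^(2 * order))
}

# 1/f amplitude shape, flattened below f_floor to keep finite power at DC
pink_shape <- function(f, exponent, f_floor = 0.5) {
  pmax(f, f_floor)^(-exponent / 2)
}

# amplitude shape laid out over full-FFT bins (symmetric in k and n-k)
full_fft_shape <- function(n, fs, shape_fun) {
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  shape_fun(f)
}

# shape white noise columns: filter in the frequency domain, unit variance out
shaped_noise <- function(n, n_series, shape) {
  x <- matrix(stats::rnorm(n * n_series), n, n_series)
  xf <- stats::mvfft(x) * shape
  y <- Re(stats::mvfft(xf, inverse = TRUE)) / n
  sc <- sqrt(colMeans(y^2) - colMeans(y)^2)
  sweep(y, 2, pmax(sc, 1e-12), "/")
}

# Expected measured band power of each unit-variance signal component.
# The planted "truth" is defined as the expectation of the analysis
# pipeline's measurement: the component's line spectrum is smeared by the
# squared spectral window of the Hann taper (Welch bias) and integrated
# with the same trapezoidal half-open band rule band_power() applies, so a
# calibration test compares like with like. All components share the same
# kernel, so common constants cancel in the relative-power normalisation.
# rows of $band: one per band component; $pink: the 1/f background.
.share_cache <- new.env(parent = emptyenv())

component_band_shares <- function(n, fs, scheme, pink_exponent, window = 2) {
  key <- paste(n, fs, window, pink_exponent,
               paste(scheme$bands$fmin, scheme$bands$fmax, collapse = ","),
               sep = "|")
  if (!is.null(.share_cache[[key]])) return(.share_cache[[key]])
  bands <- scheme$bands
  nb <- nrow(bands)
  nper <- round(window * fs)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / nper)
  wspec <- Mod(stats::fft(c(taper, rep(0, n - nper))))^2  # offsets in fs/n steps
  nj <- floor(n / 2)
  jf <- (0:nj) * fs / n                       # fine one-sided grid
  df2 <- fs / nper
  kk <- 0:(nper %/% 2)
  f2 <- kk * df2                              # analysis (Welch) bins
  # trapezoid weights per band on the analysis grid, half-open membership
  resp <- matrix(0, nj + 1, nb, dimnames = list(NULL, bands$name))
  step <- n / nper
  for (b in seq_len(nb)) {
    inb <- f2 >= bands$fmin[b] & f2 < bands$fmax[b]
    if (b == nb) inb <- inb | f2 == bands$fmax[b]
    sel <- which(inb)
    tau <- rep(df2, length(sel))
    tau[c(1, length(sel))] <- df2 / 2
    acc <- numeric(nj + 1)
    for (i in seq_along(sel)) {
      k <- kk[sel[i]]
      idx1 <- (round(k * step) - (0:nj)) %% n
      idx2 <- (round(k * step) + (0:nj)) %% n
      acc <- acc + tau[i] * (wspec[idx1 + 1] + wspec[idx2 + 1])
    }
    resp[, b] <- acc
  }
  mult <- c(1, rep(2, nj - 1), if (n %% 2 == 0) 1 else 2)
  mass_of <- function(amp) {
    m <- amp^2 * mult
    m / sum(m)
  }
  band_shares <- t(vapply(seq_len(nb), function(j)
    drop(crossprod(resp, mass_of(butter_bp_shape(jf, bands$fmin[j],
                                                 bands$fmax[j])))),
    numeric(nb)))
  dimnames(band_shares) <- list(bands$name, bands$name)
  pink <- drop(crossprod(resp, mass_of(pink_shape(jf, pink_exponent))))
  names(pink) <- bands$name
  out <- list(band = band_shares, pink = pink)
  .share_cache[[key]] <- out
  out
}

#' Planted relative band-power profile
#'
#' The exact relative band power each region is constructed to carry, given
#' the configured topography, the 1/f background, and (optionally) a patient
#' effect and per-subject band factors. This is the ground truth that the
#' full pipeline is expected to recover.
#'
#' @param config a [sim_config()].
#' @param parcellation a [make_parcellation()] result (rebuilt if `NULL`).
#' @param effect optional list(`rois`, `band`, `factor`): multiply the
#'   planted power of `band` in regions `rois` by `factor`.
#' @param band_factors optional per-band multiplicative factors (subject
#'   variability); default all 1.
#' @return ROIs x bands matrix of relative band power, rows summing to 1.
#' @export
ground_truth_profile <- function(config, parcellation = NULL, effect = NULL,
                                 band_factors = NULL) {
  if (is.null(parcellation)) parcellation <- make_parcellation(config)
  profiles <- config$band_profiles %||%
    default_band_profiles(parcellation, config$scheme)
  nb <- n_bands(config$scheme)
  w <- band_factors %||% rep(1, nb)
  p <- sweep(profiles, 2, w, "*")
  if (!is.null(effect)) {
    bi <- match(effect$band, band_names(config$scheme))
    if (is.na(bi)) stop_named("effect band '%s' not in scheme", effect$band)
    if (!all(effect$rois %in% parcellation$roi$roi_id))
      stop_named("affected ROI %d not in parcellation",
                 setdiff(effect$rois, parcellation$roi$roi_id)[1])
    p[effect$rois, bi] <- p[effect$rois, bi] * effect$factor
  }
  n <- round(config$duration * config$fs)
  sh <- component_band_shares(n, config$fs, config$scheme, config$pink_exponent)
  q <- p %*% sh$band +
    matrix(config$pink_weight * sh$pink, nrow = nrow(p), ncol = nb, byrow = TRUE)
  q / rowSums(q)
}

#' Simulate one subject's region-level source signals
#'
#' Draws per-band subject power factors (lognormal) and synthesizes one time
#' series per region: a mixture of band-limited noise components with the
#' planted per-band power plus a 1/f background. These are the ground-truth
#' source dynamics; [simulate_subject()] projects them to the sensors.
#'
#' @param config a [sim_config()].
#' @param parcellation a [make_parcellation()] result.
#' @param subject_seed integer seed for this subject's substream.
#' @param effect optional planted patient effect, see [ground_truth_profile()].
#' @return list: `ts` (a `roi_timeseries`, ROIs x samples), `band_factors`,
#'   `planted` (the subject's exact relative band-power profile).
#' @export
simulate_roi_series <- function(config, parcellation, subject_seed,
                                effect = NULL) {
  scheme <- config$scheme
  nb <- n_bands(scheme)
  nroi <- parcellation$n_rois
  n <- round(config$duration * config$fs)
  profiles <- config$band_profiles %||% default_band_profiles(parcellation, scheme)
  with_seed(subject_seed, {
    w <- exp(stats::rnorm(nb) * config$subject_sd)
    p <- sweep(profiles, 2, w, "*")
    if (!is.null(effect)) {
      bi <- match(effect$band, band_names(scheme))
      if (is.na(bi)) stop_named("effect band '%s' not in scheme", effect$band)
      if (!all(effect$rois %in% parcellation$roi$roi_id))
        stop_named("affected ROI %d not in parcellation",
                   setdiff(effect$rois, parcellation$roi$roi_id)[1])
      p[effect$rois, bi] <- p[effect$rois, bi] * effect$factor
    }
    y <- matrix(0, n, nroi)
    for (j in seq_len(nb)) {
      shape <- full_fft_shape(n, config$fs, function(f)
        butter_bp_shape(f, scheme$bands$fmin[j], scheme$bands$fmax[j]))
      y <- y + shaped_noise(n, nroi, shape) * rep(sqrt(p[, j]), each = n)
    }
    if (config$pink_weight > 0) {
      shape <- full_fft_shape(n, config$fs, function(f)
        pink_shape(f, config$pink_exponent))
      y <- y + sqrt(config$pink_weight) * shaped_noise(n, nroi, shape)
    }
  })
  ts <- structure(list(data = t(y), fs = config$fs,
                       roi_ids = parcellation$roi$roi_id,
                       roi_names = parcellation$roi$roi_name),
                  class = "roi_timeseries")
  list(ts = ts, band_factors = w,
       planted = ground_truth_profile(config, parcellation, effect,
                                      band_factors = w))
}

#' Simulate one subject's sensor recording
#'
#' Synthesizes region-level source signals with [simulate_roi_series()],
#' projects them through the leadfield, and adds white sensor noise, a
#' rank-1 quasi-periodic cardiac artifact, and an ECG channel carrying the
#' beat train. All sources of one region share the region's time series;
#' opposing sulcal-wall polarities live in the leadfield columns via the
#' source orientations.
#'
#' @param config a [sim_config()].
#' @param leadfield a [make_leadfield()] result.
#' @param parcellation a [make_parcellation()] result.
#' @param subject_seed integer seed for this subject's substream.
#' @param effect optional planted patient effect, see [ground_truth_profile()].
#' @param keep_roi_series keep the source-space ROI series in `$truth`
#'   (memory: ROIs x samples doubles).
#' @return list with `recording` (a [sensor_recording()]) and `truth`
#'   (planted relative band power, band factors, beat times, artifact
#'   topography, effect, optionally the ROI series).
#' @export
simulate_subject <- function(config, leadfield, parcellation, subject_seed,
                             effect = NULL, keep_roi_series = FALSE) {
  if (ncol(leadfield$gain) != length(parcellation$source_roi))
    stop_named("dimension mismatch on the source axis: leadfield has %d sources, parcellation maps %d",
               ncol(leadfield$gain), length(parcellation$source_roi))
  if (nrow(leadfield$gain) != config$n_sensors)
    stop_named("dimension mismatch on the sensor axis: leadfield has %d sensors, config says %d",
               nrow(leadfield$gain), config$n_sensors)
  nroi <- parcellation$n_rois
  n <- round(config$duration * config$fs)

  sim <- simulate_roi_series(config, parcellation, subject_seed, effect)
  y <- t(sim$ts$data)                     # samples x ROIs

  # aggregate leadfield by region: all sources of a region carry its series
  gain_roi <- vapply(seq_len(nroi), function(i)
    rowSums(leadfield$gain[, roi_sources(parcellation, i), drop = FALSE]),
    numeric(nrow(leadfield$gain)))

  with_seed(substream_seed(subject_seed, "sensor"), {
    sensor <- gain_roi %*% t(y)
    rms <- stats::sd(as.vector(sensor))
    sensor <- sensor + matrix(stats::rnorm(length(sensor),
                                           sd = config$sensor_noise_sd * rms),
                              nrow = nrow(sensor))
    beat_times <- numeric(0)
    topo <- rep(0, config$n_sensors)
    train <- numeric(n)
    if (isTRUE(config$artifact$enabled)) {
      rate <- config$artifact$rate_hz
      t0 <- stats::runif(1, 0, 1 / rate)
      iv <- (1 / rate) * (1 + config$artifact$jitter_sd *
                            stats::rnorm(ceiling(config$duration * rate * 1.5)))
      beat_times <- t0 + cumsum(c(0, iv))
      beat_times <- beat_times[beat_times < config$duration - 0.1]
      train <- beat_train(n, config$fs, beat_times)
      topo <- stats::rnorm(config$n_sensors)
      topo <- topo / sqrt(sum(topo^2))
      amp <- config$artifact$rel_amplitude * rms / max(stats::sd(train), 1e-12)
      sensor <- sensor + amp * topo %*% t(train)
    }
    ecg <- 500 * train + stats::rnorm(n, sd = 5)
  })
  data <- rbind(sensor, ecg)
  rec <- sensor_recording(
    data, config$fs,
    channel_names = c(leadfield$sensor_names, "ECG"),
    channel_types = c(rep("EEG", config$n_sensors), "ECG"))
  truth <- list(
    roi_band_power = sim$planted,
    band_factors = sim$band_factors, effect = effect,
    beat_times = beat_times, artifact_topography = topo,
    roi_series = if (keep_roi_series) sim$ts else NULL)
  list(recording = rec, truth = truth)
}

# QRS-like biphasic template train (derivative-of-Gaussian, ~25 ms sigma
# scaled peak), placed at the given beat times
beat_train <- function(n, fs, beat_times, sigma = 0.012) {
  half <- round(5 * sigma * fs)
  tt <- (-half:half) / fs
  tmpl <- -tt / sigma^2 * exp(-tt^2 / (2 * sigma^2))
  tmpl <- tmpl / max(abs(tmpl))
  train <- numeric(n)
  for (bt in beat_times) {
    c0 <- round(bt * fs) + 1
    idx <- (c0 - half):(c0 + half)
    keep <- idx >= 1 & idx <= n
    train[idx[keep]] <- train[idx[keep]] + tmpl[keep]
  }
  train
}

#' Simulate the healthy and patient cohorts
#'
#' Healthy subjects follow the planted normative topography; patients are
#' generated identically except that the planted power of the configured
#' band is multiplied by the effect factor in the affected temporal regions
#' of their epileptogenic hemisphere. The left/right split of epileptogenic
#' sides defaults to the 14:8 proportion of the study cohort.
#'
#' @param config a [sim_config()].
#' @return object of class `cohort_sim`: `$healthy` and `$patients` (lists of
#'   [simulate_subject()] results), `$truth` (base planted profile, patient
#'   sides, affected pairs/band/factor), `$leadfield`, `$parcellation`.
#' @export
simulate_cohorts <- function(config) {
  validate_sim_config(config)
  parc <- make_parcellation(config)
  lf <- make_leadfield(config)
  tp <- temporal_pairs(parc)
  ne <- config$patient_effect$n_pairs
  if (ne > nrow(tp))
    stop_named("patient_effect$n_pairs (%d) exceeds temporal pairs (%d)", ne, nrow(tp))
  aff <- tp[seq_len(ne), , drop = FALSE]
  n_left <- round(config$n_patients * 14 / 22)
  sides <- with_seed(substream_seed(config$seed, "sides"),
                     sample(rep(c("L", "R"), c(n_left, config$n_patients - n_left))))
  healthy <- lapply(seq_len(config$n_healthy), function(i)
    simulate_subject(config, lf, parc,
                     substream_seed(config$seed, "healthy", i)))
  patients <- lapply(seq_len(config$n_patients), function(i) {
    rois <- if (sides[i] == "L") aff$roi_left else aff$roi_right
    simulate_subject(config, lf, parc,
                     substream_seed(config$seed, "patient", i),
                     effect = list(rois = rois,
                                   band = config$patient_effect$band,
                                   factor = config$patient_effect$factor))
  })
  structure(list(
    healthy = healthy, patients = patients,
    truth = list(roi_band_power = ground_truth_profile(config, parc),
                 patient_sides = sides, affected_pairs = aff$pair_id,
                 affected_band = config$patient_effect$band,
                 effect_factor = config$patient_effect$factor),
    leadfield = lf, parcellation = parc, config = config),
    class = "cohort_sim")
}

#' Fast cohort simulation at the band-power-table level
#'
#' Skips the signal chain entirely: draws relative band-power maps directly
#' from the planted profile with per-subject band factors (lognormal,
#' `subject_sd`) and per-cell lognormal noise (`welch_noise_sd`) emulating
#' spectral estimation error. Used for replicate-heavy calibration studies
#' where simulating thousands of recordings would be pointless.
#'
#' @param config a [sim_config()].
#' @param n_subjects number of maps to draw.
#' @param effect optional planted effect, see [ground_truth_profile()].
#' @param seed integer seed.
#' @param parcellation optional pre-built parcellation.
#' @return list of ROIs x bands relative band-power matrices (rows sum to 1).
#' @export
simulate_bandpower_cohort <- function(config, n_subjects, effect = NULL,
                                      seed = config$seed,
                                      parcellation = NULL) {
  if (is.null(parcellation)) parcellation <- make_parcellation(config)
  profiles <- config$band_profiles %||%
    default_band_profiles(parcellation, config$scheme)
  nb <- n_bands(config$scheme)
  n <- round(config$duration * config$fs)
  sh <- component_band_shares(n, config$fs, config$scheme, config$pink_exponent)
  p0 <- profiles
  if (!is.null(effect)) {
    bi <- match(effect$band, band_names(config$scheme))
    p0[effect$rois, bi] <- p0[effect$rois, bi] * effect$factor
  }
  pinkq <- config$pink_weight * sh$pink
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      w <- exp(stats::rnorm(nb) * config$subject_sd)
      q <- sweep(p0, 2, w, "*") %*% sh$band +
        matrix(pinkq, nrow = nrow(p0), ncol = nb, byrow = TRUE)
      q <- q * matrix(exp(stats::rnorm(length(q)) * config$welch_noise_sd),
                      nrow = nrow(q))
      x <- q / rowSums(q)
      dimnames(x) <- list(parcellation$roi$roi_name, band_names(config$scheme))
      x
    })
  })
}
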