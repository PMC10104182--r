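#' Simulation configuration
#'
#' Parameters of the synthetic study: a healthy normative cohort and a
#' temporal-lobe-epilepsy cohort of eyes-closed resting recordings with known
#' planted band-power topographies. Defaults emulate the study conditions:
#' 30 scalp channels at 250 Hz, 120 s recordings, a 114-region neocortical
#' parcellation of which 6 regions have no homologue (so 54 left/right pairs)
#' and 13 pairs are temporal-lobe, 17 healthy subjects and 22 patients with a
#' planted ipsilateral temporal delta-power abnormality.
#'
#' @param n_sensors number of EEG channels (an ECG channel is appended).
#' @param n_sources number of constrained cortical sources.
#' @param n_rois number of parcellation regions.
#' @param n_unpaired_rois regions without a left/right homologue.
#' @param n_temporal_pairs homologous pairs labelled temporal-lobe.
#' @param fs sampling rate, Hz.
#' @param duration recording length, seconds.
#' @param band_profiles optional ROIs x bands matrix of planted band-power
#'   weights (rows need not be normalised); `NULL` uses the default
#'   topography (posterior alpha, anterior/temporal delta).
#' @param pink_exponent spectral slope of the 1/f background.
#' @param pink_weight power of the 1/f background relative to unit total
#'   oscillatory power per region.
#' @param subject_sd log-scale SD of the per-subject, per-band power factor
#'   (inter-subject variability; a free choice, the study data do not
#'   quantify it).
#' @param welch_noise_sd log-scale SD of per-cell band-power noise used only
#'   by the fast table-level simulator [simulate_bandpower_cohort()],
#'   emulating spectral estimation noise.
#' @param sensor_noise_sd white sensor noise amplitude relative to the RMS of
#'   the clean sensor signal.
#' @param artifact list: `enabled`, `rate_hz` (cardiac rate, default 1.1 Hz),
#'   `rel_amplitude` (artifact RMS relative to clean sensor RMS),
#'   `jitter_sd` (relative beat-interval jitter).
#' @param n_healthy,n_patients cohort sizes.
#' @param patient_effect list: `factor` (multiplicative power change),
#'   `band` (affected band), `n_pairs` (number of most-anterior temporal
#'   pairs affected on the epileptogenic side).
#' @param scheme a [band_scheme()].
#' @param seed root RNG seed; all stages draw named substreams from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_sensors = 30, n_sources = 400, n_rois = 114,
                       n_unpaired_rois = 6, n_temporal_pairs = 13,
                       fs = 250, duration = 120,
                       band_profiles = NULL,
                       pink_exponent = 1.0, pink_weight = 0.4,
                       subject_sd = 0.07, welch_noise_sd = 0.13,
                       sensor_noise_sd = 0.05,
                       artifact = list(enabled = TRUE, rate_hz = 1.1,
                                       rel_amplitude = 2.0, jitter_sd = 0.03),
                       n_healthy = 17, n_patients = 22,
                       patient_effect = list(factor = 3, band = "delta",
                                             n_pairs = 2),
                       scheme = band_scheme(), seed = 1L) {
  cfg <- list(n_sensors = n_sensors, n_sources = n_sources, n_rois = n_rois,
              n_unpaired_rois = n_unpaired_rois,
              n_temporal_pairs = n_temporal_pairs,
              fs = fs, duration = duration, band_profiles = band_profiles,
              pink_exponent = pink_exponent, pink_weight = pink_weight,
              subject_sd = subject_sd, welch_noise_sd = welch_noise_sd,
              sensor_noise_sd = sensor_noise_sd,
              artifact = utils::modifyList(
                list(enabled = TRUE, rate_hz = 1.1, rel_amplitude = 2.0,
                     jitter_sd = 0.03), artifact %||% list()),
              n_healthy = n_healthy, n_patients = n_patients,
              patient_effect = utils::modifyList(
                list(factor = 3, band = "delta", n_pairs = 2),
                patient_effect %||% list()),
              scheme = scheme, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  np <- (cfg$n_rois - cfg$n_unpaired_rois) / 2
  if (np != floor(np) || np < 1)
    stop_named("n_rois (%d) minus n_unpaired_rois (%d) must be an even positive count",
               cfg$n_rois, cfg$n_unpaired_rois)
  if (cfg$n_temporal_pairs > np)
    stop_named("n_temporal_pairs (%d) exceeds available pairs (%d)",
               cfg$n_temporal_pairs, np)
  if (cfg$n_sources < cfg$n_rois)
    stop_named("n_sources (%d) < n_rois (%d): every ROI needs at least one source",
               cfg$n_sources, cfg$n_rois)
  if (cfg$n_sensors < 4) stop_named("n_sensors must be >= 4")
  top <- max(cfg$scheme$bands$fmax)
  if (cfg$fs <= 2 * top)
    stop_named("fs (%g) must exceed twice the highest band edge (%g)", cfg$fs, top)
  if (cfg$patient_effect$factor <= 0) stop_named("patient effect factor must be > 0")
  if (!cfg$patient_effect$band %in% band_names(cfg$scheme))
    stop_named("patient effect band '%s' not in the band scheme", cfg$patient_effect$band)
  invisible(cfg)
}

n_pairs <- function(cfg) (cfg$n_rois - cfg$n_unpaired_rois) %/% 2

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d sensors, %d sources, %d ROIs (%d pairs, %d unpaired, %d temporal pairs)\n",
              x$n_sensors, x$n_sources, x$n_rois, n_pairs(x),
              x$n_unpaired_rois, x$n_temporal_pairs))
  cat(sprintf("  %g Hz x %g s; cohorts %d healthy / %d patients; seed %d\n",
              x$fs, x$duration, x$n_healthy, x$n_patients, x$seed))
  invisible(x)
}
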