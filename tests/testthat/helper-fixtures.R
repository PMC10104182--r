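# Shared fixtures: small configurations keep unit tests fast; the
# full-scale study conditions are exercised in test-acceptance.R.

toy_config <- function(seed = 7, ...) {
  sim_config(n_sensors = 12, n_sources = 60, n_rois = 20,
             n_unpaired_rois = 2, n_temporal_pairs = 4,
             duration = 40, n_healthy = 3, n_patients = 2,
             seed = seed, ...)
}

# single-channel roi_timeseries carrying the given signal(s)
ts_of <- function(x, fs = 250, names = NULL) {
  m <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  structure(list(data = m, fs = fs,
                 roi_names = names %||% sprintf("r%02d", seq_len(nrow(m)))),
            class = "roi_timeseries")
}

sine_wave <- function(freq, fs = 250, duration = 60, amplitude = 1, phase = 0) {
  amplitude * sin(2 * pi * freq * (0:(round(duration * fs) - 1)) / fs + phase)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# synthetic ECG-only recording with known beat times (bpm beats per minute)
ecg_recording <- function(bpm = 72, duration = 60, fs = 250, n_eeg = 4,
                          seed = 1) {
  set.seed(seed)
  period <- 60 / bpm
  beats <- seq(0.5, duration - 0.5, by = period)
  n <- round(duration * fs)
  train <- eegnorm:::beat_train(n, fs, beats)
  eeg <- matrix(rnorm(n_eeg * n), n_eeg)
  rec <- sensor_recording(rbind(eeg, 400 * train + rnorm(n, sd = 2)), fs,
                          channel_names = c(sprintf("E%d", seq_len(n_eeg)), "ECG"),
                          channel_types = c(rep("EEG", n_eeg), "ECG"))
  list(rec = rec, beats = beats)
}
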