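#' Resample a recording
#'
#' Anti-alias low-pass followed by resampling. Downsampling only (the
#' pipeline never upsamples). An order-8 zero-phase Butterworth low-pass at
#' 80% of the target Nyquist precedes decimation; integer factors decimate
#' directly, non-integer ratios evaluate the band-limited signal on the new
#' sample grid by cubic-spline interpolation.
#'
#' @param rec a [sensor_recording()].
#' @param target_fs target sampling rate, Hz.
#' @return the resampled recording.
#' @export
resample_recording <- function(rec, target_fs) {
  if (target_fs > rec$fs)
    stop_named("target_fs (%g) exceeds fs (%g): upsampling not supported",
               target_fs, rec$fs)
  if (target_fs == rec$fs) return(rec)
  bf <- signal::butter(8, 0.8 * target_fs / rec$fs, type = "low")
  filt <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  ratio <- rec$fs / target_fs
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1, ncol(filt), by = round(ratio))
    out <- filt[, idx, drop = FALSE]
  } else {
    t_old <- (seq_len(ncol(filt)) - 1) / rec$fs
    t_new <- seq(0, t_old[length(t_old)], by = 1 / target_fs)
    out <- t(apply(filt, 1, function(x)
      stats::spline(t_old, x, xout = t_new)$y))
  }
  rec$data <- out
  rownames(rec$data) <- rec$channel_names
  rec$fs <- target_fs
  rec
}

#' Zero-phase Butterworth band-pass
#'
#' Order-4 (per pass) Butterworth applied forward and backward
#' ([signal::filtfilt()]), giving a flat passband and no phase distortion.
#' The study range is 0.5-47.5 Hz.
#'
#' @param rec a [sensor_recording()].
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order filter order per pass.
#' @return the filtered recording.
#' @export
bandpass_recording <- function(rec, low = 0.5, high = 47.5, order = 4) {
  nyq <- rec$fs / 2
  if (high >= nyq)
    stop_named("high edge (%g Hz) must be below Nyquist (%g Hz)", high, nyq)
  if (low <= 0 || low >= high)
    stop_named("need 0 < low < high (got %g, %g)", low, high)
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  rec$data <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  rownames(rec$data) <- rec$channel_names
  rec$reference <- rec$reference
  rec
}

#' Common average reference
#'
#' Subtracts the per-sample mean of the good EEG channels from every EEG
#' channel. ECG/EOG and bad channels are untouched.
#'
#' @param rec a [sensor_recording()].
#' @return the re-referenced recording.
#' @export
common_average_reference <- function(rec) {
  good <- good_eeg_channels(rec)
  if (length(good) < 2)
    stop_named("common average reference needs >= 2 good EEG channels (have %d)",
               length(good))
  avg <- colMeans(rec$data[good, , drop = FALSE])
  eeg <- which(rec$channel_types == "EEG")
  rec$data[eeg, ] <- sweep(rec$data[eeg, , drop = FALSE], 2, avg)
  rec$reference <- "common average"
  rec
}

#' Drop the settling period at the start of a recording
#'
#' The first seconds of a session (subject settling) are not analysed.
#'
#' @param rec a [sensor_recording()].
#' @param seconds duration to discard (default 30).
#' @return the shortened recording.
#' @export
discard_settle <- function(rec, seconds = 30) {
  drop_n <- round(seconds * rec$fs)
  if (drop_n >= ncol(rec$data))
    stop_named("cannot discard %g s from a %.1f s recording",
               seconds, rec_duration(rec))
  if (drop_n > 0) rec$data <- rec$data[, -seq_len(drop_n), drop = FALSE]
  rec
}
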