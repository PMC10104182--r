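#' Multichannel sensor recording
#'
#' Container for a sensor-space recording: a channels x samples matrix in
#' microvolts, the sampling rate, and per-channel metadata (name, type, bad
#' flag). EEG channels carry brain signal; an ECG channel, when present, is
#' used for cardiac artifact detection and is excluded from referencing,
#' projection and inverse modelling.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_names character vector, one per row of `data`.
#' @param channel_types character vector of "EEG", "ECG" or "EOG".
#' @param bad_channels character subset of `channel_names` to exclude from
#'   analysis (not interpolated).
#' @param reference free-text provenance tag for the reference state.
#' @return an object of class `sensor_recording`.
#' @export
sensor_recording <- function(data, fs, channel_names = NULL,
                             channel_types = NULL, bad_channels = character(),
                             reference = "as-recorded") {
  data <- as.matrix(data)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_named("fs must be a single positive number")
  nch <- nrow(data)
  if (is.null(channel_names))
    channel_names <- sprintf("Ch%02d", seq_len(nch))
  if (is.null(channel_types))
    channel_types <- rep("EEG", nch)
  if (length(channel_names) != nch)
    stop_named("channel_names length (%d) != number of data rows (%d)",
               length(channel_names), nch)
  if (length(channel_types) != nch)
    stop_named("channel_types length (%d) != number of data rows (%d)",
               length(channel_types), nch)
  if (anyDuplicated(channel_names))
    stop_named("duplicate channel names")
  if (!all(bad_channels %in% channel_names))
    stop_named("bad_channels not among channel_names: %s",
               paste(setdiff(bad_channels, channel_names), collapse = ", "))
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 channel_types = channel_types,
                 bad_channels = as.character(bad_channels),
                 reference = reference),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  types:", paste(sprintf("%s:%d", names(table(x$channel_types)),
                                table(x$channel_types)), collapse = " "),
      " reference:", x$reference, "\n")
  if (length(x$bad_channels))
    cat("  bad:", paste(x$bad_channels, collapse = ", "), "\n")
  invisible(x)
}

#' Indices of usable EEG channels
#'
#' @param rec a `sensor_recording`.
#' @return integer indices of channels typed "EEG" and not flagged bad.
#' @export
good_eeg_channels <- function(rec) {
  which(rec$channel_types == "EEG" & !(rec$channel_names %in% rec$bad_channels))
}

n_samples <- function(rec) ncol(rec$data)

#' Duration of a recording in seconds
#' @param rec a `sensor_recording`.
#' @return seconds.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$fs

#' Standard 30-channel 10-20 montage labels
#'
#' The extended 10-20 label set used for simulated scalp recordings.
#' @return character vector of length 30.
#' @export
montage_1020_30 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
    "PO3", "PO4", "O1", "Oz", "O2")
}
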