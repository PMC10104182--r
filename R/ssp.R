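#' Detect heartbeats on the ECG channel
#'
#' Envelope-threshold R-peak detector (Pan-Tompkins-like): band-pass
#' 5-35 Hz, squaring, centred moving-average envelope (150 ms), adaptive
#' threshold at mean + 2 SD of the envelope, peak refinement to the maximum
#' of the squared band-passed ECG within each supra-threshold region, and a
#' 0.3 s refractory period. A flat ECG yields no events.
#'
#' @param rec a [sensor_recording()] containing an ECG-typed channel.
#' @param band detector pass band, Hz.
#' @param refractory minimum inter-beat interval, seconds.
#' @return object of class `event_series`: `$times` (sample indices, strictly
#'   increasing), `$kind = "heartbeat"`.
#' @export
detect_heartbeats <- function(rec, band = c(5, 35), refractory = 0.3) {
  ecg_i <- which(rec$channel_types == "ECG")
  if (!length(ecg_i)) stop_named("no ECG channel in recording")
  x <- rec$data[ecg_i[1], ]
  nyq <- rec$fs / 2
  bf <- signal::butter(3, pmin(band, nyq * 0.99) / nyq, type = "pass")
  xf <- signal::filtfilt(bf, x)
  sq <- xf^2
  w <- max(3L, round(0.15 * rec$fs))
  if (w %% 2 == 0) w <- w + 1L
  env <- stats::filter(sq, rep(1 / w, w), sides = 2)
  env[is.na(env)] <- 0
  thr <- mean(env) + 2 * stats::sd(env)
  above <- env > thr
  if (!any(above)) return(event_series(integer(0)))
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1L
  peaks <- vapply(seq_along(starts), function(i) {
    seg <- starts[i]:ends[i]
    seg[which.max(sq[seg])]
  }, 0L)
  peaks <- sort(peaks)
  refr <- round(refractory * rec$fs)
  kept <- peaks[1]
  for (p in peaks[-1]) if (p - kept[length(kept)] >= refr) kept <- c(kept, p)
  event_series(kept)
}

#' Event series
#' @param times integer sample indices, strictly increasing.
#' @param kind event label.
#' @return an `event_series`.
#' @export
event_series <- function(times, kind = "heartbeat") {
  times <- as.integer(times)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop_named("event times must be strictly increasing")
  structure(list(times = times, kind = kind), class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %d '%s' events\n", length(x$times), x$kind))
  invisible(x)
}

#' Fit a signal-space projector from artifact-locked epochs
#'
#' Epochs of the EEG channels centred on the events are averaged (classic
#' artifact-locked average) and the left singular vectors of the average
#' taken as the artifact's channel-space basis. The explained-variance
#' fraction of each component is reported so the operator's choice of `k`
#' (the study selected components manually) can be made on a quantified
#' basis.
#'
#' @param rec a [sensor_recording()].
#' @param events an [event_series()].
#' @param window epoch half-width in seconds (epoch = event +- window).
#' @param k number of components to keep.
#' @return object of class `ssp_projector`: `$components` (channels x k,
#'   orthonormal), `$explained` (variance fractions, all components),
#'   `$channel_names`, `$kind`.
#' @export
fit_ssp <- function(rec, events, window = 0.2, k = 1) {
  eeg <- which(rec$channel_types == "EEG")
  half <- round(window * rec$fs)
  usable <- events$times[events$times - half >= 1 &
                           events$times + half <= ncol(rec$data)]
  if (length(usable) < 5)
    stop_named("need >= 5 events fully inside the recording (have %d)",
               length(usable))
  acc <- matrix(0, length(eeg), 2 * half + 1)
  for (t0 in usable)
    acc <- acc + rec$data[eeg, (t0 - half):(t0 + half), drop = FALSE]
  acc <- acc / length(usable)
  sv <- svd(acc)
  expl <- sv$d^2 / sum(sv$d^2)
  comps <- sv$u[, seq_len(min(k, ncol(sv$u))), drop = FALSE]
  if (k == 0) comps <- matrix(0, length(eeg), 0)
  structure(list(components = comps, explained = expl,
                 channel_names = rec$channel_names[eeg], kind = "cardiac"),
            class = "ssp_projector")
}

#' Apply a signal-space projector
#'
#' Projects the EEG channels onto the orthogonal complement of the artifact
#' subspace: `data <- (I - U U') data`. Idempotent; never increases power.
#'
#' @param rec a [sensor_recording()].
#' @param proj an [fit_ssp()] result.
#' @return the projected recording.
#' @export
apply_ssp <- function(rec, proj) {
  eeg <- which(rec$channel_types == "EEG")
  if (!identical(proj$channel_names, rec$channel_names[eeg]))
    stop_named("projector channels do not match recording EEG channels")
  if (ncol(proj$components) == 0) return(rec)
  u <- proj$components
  d <- rec$data[eeg, , drop = FALSE]
  rec$data[eeg, ] <- d - u %*% (t(u) %*% d)
  rec
}
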