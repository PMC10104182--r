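#' Select a contiguous epoch from ROI time series
#'
#' The normative analysis uses one 60-second continuous epoch per recording;
#' the robustness analysis uses 30-second non-overlapping epochs.
#'
#' @param ts a `roi_timeseries` (or `sensor_recording`; anything with `$data`
#'   and `$fs`).
#' @param start epoch start in seconds (0 = first sample).
#' @param duration epoch length in seconds (default 60).
#' @return the sliced object.
#' @export
select_epoch <- function(ts, start = 0, duration = 60) {
  n <- ncol(ts$data)
  i0 <- round(start * ts$fs) + 1
  i1 <- i0 + round(duration * ts$fs) - 1
  if (i0 < 1 || i1 > n)
    stop_named("epoch [%g, %g] s exceeds the %.1f s recording",
               start, start + duration, n / ts$fs)
  ts$data <- ts$data[, i0:i1, drop = FALSE]
  ts
}

#' Non-overlapping epoch plan
#'
#' Start times of `n_epochs` back-to-back epochs of `duration` seconds,
#' beginning at the earliest valid sample.
#'
#' @param total_duration available duration, seconds.
#' @param duration epoch length, seconds (default 30).
#' @param n_epochs number of epochs (default 3).
#' @return numeric vector of start times (seconds).
#' @export
epoch_plan <- function(total_duration, duration = 30, n_epochs = 3) {
  if (n_epochs * duration > total_duration + 1e-9)
    stop_named("%d x %g s epochs do not fit in %g s", n_epochs, duration,
               total_duration)
  seq(0, by = duration, length.out = n_epochs)
}

#' Welch power spectral density of ROI time series
#'
#' Averaged modified periodograms: Hann-tapered segments of `window` seconds
#' with fractional `overlap`, density scaling (uV^2/Hz) such that the
#' integral over frequency approximates the signal variance.
#'
#' @param ts a `roi_timeseries` (rows = ROIs).
#' @param window segment length in seconds (default 2).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5).
#' @return object of class `spectrum_welch`: `$freqs` (Hz), `$psd`
#'   (ROIs x freqs), `$window`, `$overlap`.
#' @export
welch_psd <- function(ts, window = 2, overlap = 0.5) {
  n <- ncol(ts$data)
  nper <- round(window * ts$fs)
  if (n < nper)
    stop_named("series (%d samples) shorter than one %g s window (%d samples)",
               n, window, nper)
  hop <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1, n - nper + 1, by = hop)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / nper)  # periodic Hann
  u <- sum(taper^2)
  nfreq <- nper %/% 2 + 1
  freqs <- (seq_len(nfreq) - 1) * ts$fs / nper
  nroi <- nrow(ts$data)
  acc <- matrix(0, nroi, nfreq)
  for (s0 in starts) {
    seg <- ts$data[, s0:(s0 + nper - 1), drop = FALSE] * rep(taper, each = nroi)
    ft <- stats::mvfft(t(seg))[seq_len(nfreq), , drop = FALSE]
    acc <- acc + t(Mod(ft)^2)
  }
  psd <- acc / (length(starts) * u * ts$fs)
  # one-sided: double everything except DC (and Nyquist when nper is even)
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nper %% 2 == 0) dbl[nfreq] <- 1
  psd <- sweep(psd, 2, dbl, "*")
  structure(list(freqs = freqs, psd = psd, window = window, overlap = overlap,
                 fs = ts$fs,
                 roi_names = ts$roi_names %||% rownames(ts$data)),
            class = "spectrum_welch")
}

#' @export
print.spectrum_welch <- function(x, ...) {
  cat(sprintf("<spectrum_welch> %d ROIs x %d freqs (0-%g Hz), %g s window, %g%% overlap\n",
              nrow(x$psd), length(x$freqs), max(x$freqs), x$window,
              100 * x$overlap))
  invisible(x)
}

#' Absolute band power by trapezoidal integration
#'
#' Integrates the PSD over the bins of each band under the half-open
#' convention `fmin <= f < fmax` (the last band includes its upper edge), so
#' shared band edges are counted exactly once.
#'
#' @param spec a [welch_psd()] result.
#' @param scheme a [band_scheme()].
#' @return ROIs x bands matrix of absolute power (uV^2).
#' @export
band_power <- function(spec, scheme = band_scheme()) {
  bands <- scheme$bands
  nb <- nrow(bands)
  out <- matrix(0, nrow(spec$psd), nb,
                dimnames = list(spec$roi_names, bands$name))
  for (j in seq_len(nb)) {
    inb <- spec$freqs >= bands$fmin[j] & spec$freqs < bands$fmax[j]
    if (j == nb) inb <- inb | spec$freqs == bands$fmax[j]
    if (sum(inb) < 2)
      stop_named("band '%s' [%g, %g) Hz covers < 2 frequency bins",
                 bands$name[j], bands$fmin[j], bands$fmax[j])
    f <- spec$freqs[inb]
    out[, j] <- apply(spec$psd[, inb, drop = FALSE], 1,
                      function(p) pracma::trapz(f, p))
  }
  out
}

#' Relative band power map
#'
#' `x_ij = P_ij / sum_j P_ij`: each region's absolute band powers divided by
#' that region's total power over the analysed bands, so rows sum to 1.
#'
#' @param abs_power ROIs x bands absolute power matrix.
#' @param subject_id label stored on the map.
#' @param epoch optional `c(start, duration)` provenance, seconds.
#' @return object of class `band_power_map`: `$values` (row-stochastic
#'   matrix), `$subject_id`, `$epoch`.
#' @export
relative_band_power <- function(abs_power, subject_id = "subject",
                                epoch = NULL) {
  tot <- rowSums(abs_power)
  if (any(tot <= 0)) {
    bad <- rownames(abs_power)[tot <= 0] %||% as.character(which(tot <= 0))
    stop_named("zero total power in ROI %s", bad[1])
  }
  structure(list(values = abs_power / tot, subject_id = subject_id,
                 epoch = epoch),
            class = "band_power_map")
}

#' @export
print.band_power_map <- function(x, ...) {
  cat(sprintf("<band_power_map> '%s': %d ROIs x %d bands\n",
              x$subject_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Full spectral stage: epoch, Welch, integrate, normalise
#'
#' Convenience wrapper from ROI time series to a relative band-power map.
#'
#' @param ts a `roi_timeseries`.
#' @param scheme a [band_scheme()].
#' @param epoch_start,epoch_duration epoch selection, seconds.
#' @param window,overlap Welch parameters.
#' @param subject_id label for the map.
#' @return a [relative_band_power()] map.
#' @export
bandpower_map <- function(ts, scheme = band_scheme(), epoch_start = 0,
                          epoch_duration = 60, window = 2, overlap = 0.5,
                          subject_id = "subject") {
  ep <- select_epoch(ts, epoch_start, epoch_duration)
  spec <- welch_psd(ep, window = window, overlap = overlap)
  relative_band_power(band_power(spec, scheme), subject_id = subject_id,
                      epoch = c(epoch_start, epoch_duration))
}
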