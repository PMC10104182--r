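#' Frequency band scheme
#'
#' The five classical EEG bands used throughout: delta 1-4, theta 4-8,
#' alpha 8-13, beta 13-30 and gamma 30-47.5 Hz. Band membership is half-open
#' (`fmin <= f < fmax`) so shared edges belong to exactly one band; the last
#' band additionally includes its upper edge. Analysis is restricted to
#' 0.5-47.5 Hz (above that, scalp signal degrades and mains artifact
#' dominates).
#'
#' @param bands data.frame with columns `name`, `fmin`, `fmax` (Hz). Default
#'   is the five-band scheme above.
#' @param total_range numeric length-2, full analysed range in Hz.
#' @return an object of class `band_scheme`.
#' @examples
#' band_scheme()
#' @export
band_scheme <- function(bands = NULL, total_range = c(0.5, 47.5)) {
  if (is.null(bands)) {
    bands <- data.frame(
      name = c("delta", "theta", "alpha", "beta", "gamma"),
      fmin = c(1, 4, 8, 13, 30),
      fmax = c(4, 8, 13, 30, 47.5),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("name", "fmin", "fmax") %in% names(bands)))
  if (any(bands$fmin >= bands$fmax))
    stop_named("band '%s' has fmin >= fmax", bands$name[bands$fmin >= bands$fmax][1])
  o <- order(bands$fmin)
  bands <- bands[o, , drop = FALSE]
  if (nrow(bands) > 1 && any(bands$fmin[-1] < bands$fmax[-nrow(bands)]))
    stop_named("bands overlap under the half-open convention")
  if (min(bands$fmin) < total_range[1] || max(bands$fmax) > total_range[2])
    stop_named("bands must lie within the total range [%g, %g] Hz",
               total_range[1], total_range[2])
  structure(list(bands = bands, total_range = total_range),
            class = "band_scheme")
}

#' @export
print.band_scheme <- function(x, ...) {
  cat("Band scheme over", x$total_range[1], "-", x$total_range[2], "Hz\n")
  print(x$bands, row.names = FALSE)
  invisible(x)
}

n_bands <- function(scheme) nrow(scheme$bands)
band_names <- function(scheme) scheme$bands$name
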