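#' Write / read a sensor recording as TSV
#'
#' Wide tab-separated layout (first columns: channel name, type, bad flag;
#' then one column per sample) with a `# fs=<Hz>` header line. Intended for
#' interchange of short recordings; EDF is available for standard tooling.
#'
#' @param rec a [sensor_recording()].
#' @param path TSV path.
#' @return `path` invisibly; `read_recording_tsv` returns the recording.
#' @export
write_recording_tsv <- function(rec, path) {
  con <- file(path, "w")
  writeLines(sprintf("# fs=%.10g reference=%s", rec$fs, rec$reference), con)
  close(con)
  tab <- data.table::data.table(
    channel = rec$channel_names, type = rec$channel_types,
    bad = rec$channel_names %in% rec$bad_channels)
  tab <- cbind(tab, data.table::as.data.table(rec$data))
  data.table::fwrite(tab, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_recording_tsv
#' @export
read_recording_tsv <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!grepl("^# fs=", hdr)) stop_named("missing '# fs=' header in %s", path)
  fs <- as.numeric(sub("^# fs=([0-9.eE+-]+).*", "\\1", hdr))
  ref <- sub("^.*reference=", "", hdr)
  tab <- data.table::fread(path, sep = "\t", skip = 1)
  sensor_recording(as.matrix(tab[, -(1:3)]), fs,
                   channel_names = tab$channel, channel_types = tab$type,
                   bad_channels = tab$channel[tab$bad],
                   reference = ref)
}

#' Write band-power maps as long TSV
#'
#' Columns: subject, roi, band, value.
#'
#' @param maps list of [relative_band_power()] maps.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_bandpower_maps <- function(maps, path) {
  tabs <- lapply(maps, function(m) {
    v <- m$values
    data.frame(subject = m$subject_id,
               roi = rep(rownames(v) %||% seq_len(nrow(v)), times = ncol(v)),
               band = rep(colnames(v) %||% seq_len(ncol(v)), each = nrow(v)),
               value = as.vector(v))
  })
  utils::write.table(do.call(rbind, tabs), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write simulation ground truth as JSON
#'
#' @param truth the `$truth` element of a [simulate_cohorts()] result.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}
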