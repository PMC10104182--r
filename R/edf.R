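# Minimal EDF/EDF+ (16-bit) ingestion. Only continuous recordings with a
# common sampling rate across signals are mapped onto sensor_recording;
# annotation channels are not parsed.

edf_field <- function(con, nchars) trimws(rawToChar(readBin(con, "raw", nchars)))

edf_pad <- function(x, width) {
  s <- formatC(as.character(x), width = width, flag = "-")
  if (nchar(s) > width) stop_named("EDF header field too long: '%s'", x)
  s
}

# shortest %g representation of a number that fits an EDF numeric field
edf_num <- function(v, width = 8) {
  for (d in 7:1) {
    s <- formatC(v, digits = d, format = "g")
    if (nchar(s) <= width) return(s)
  }
  stop_named("cannot represent %g in %d characters", v, width)
}

#' Read an EDF/EDF+ file into a sensor recording
#'
#' Supports the common case: 16-bit continuous EDF where every signal shares
#' one sampling rate. Signals whose label contains "ECG"/"EKG" or "EOG" are
#' typed accordingly; all others are typed EEG.
#'
#' @param path path to an `.edf` file.
#' @return a [sensor_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edf_field(con, 8)
  if (version != "0") stop_named("not an EDF file (version field '%s')", version)
  edf_field(con, 80); edf_field(con, 80)          # patient, recording ids
  edf_field(con, 8);  edf_field(con, 8)           # date, time
  edf_field(con, 8)                               # header length
  edf_field(con, 44)                              # reserved
  n_rec <- as.integer(edf_field(con, 8))
  rec_dur <- as.numeric(edf_field(con, 8))
  ns <- as.integer(edf_field(con, 4))
  if (is.na(ns) || ns < 1) stop_named("EDF header: bad signal count")
  rd <- function(w) vapply(seq_len(ns), function(i) edf_field(con, w), "")
  labels <- rd(16); rd(80)
  rd(8)                                            # physical dimension
  pmin <- as.numeric(rd(8)); pmax <- as.numeric(rd(8))
  dmin <- as.numeric(rd(8)); dmax <- as.numeric(rd(8))
  rd(80)                                           # prefiltering
  nsamp <- as.integer(rd(8)); rd(32)
  if (length(unique(nsamp)) != 1L)
    stop_named("EDF signals have differing per-record sample counts; not supported")
  npr <- nsamp[1]
  fs <- npr / rec_dur
  data <- matrix(0, nrow = ns, ncol = npr * n_rec)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = npr * ns, size = 2, endian = "little")
    m <- matrix(block, nrow = npr, ncol = ns)
    idx <- ((r - 1) * npr + 1):(r * npr)
    data[, idx] <- t(m) * scale + (pmin - dmin * scale)
  }
  types <- ifelse(grepl("ECG|EKG", labels, ignore.case = TRUE), "ECG",
                  ifelse(grepl("EOG", labels, ignore.case = TRUE), "EOG", "EEG"))
  sensor_recording(data, fs, channel_names = make.unique(labels),
                   channel_types = types, reference = "as-recorded (EDF)")
}

#' Write a sensor recording as 16-bit EDF
#'
#' Quantises each channel over its own physical range; intended for
#' interchange and round-trip testing, not for archival precision.
#'
#' @param rec a [sensor_recording()].
#' @param path output path.
#' @param record_duration seconds per EDF data record; must divide the
#'   recording duration evenly after rounding to samples.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_duration = 1) {
  npr <- round(record_duration * rec$fs)
  n <- ncol(rec$data)
  n_rec <- floor(n / npr)
  if (n_rec < 1) stop_named("recording shorter than one EDF record")
  ns <- nrow(rec$data)
  pmin <- apply(rec$data[, seq_len(n_rec * npr), drop = FALSE], 1, min)
  pmax <- apply(rec$data[, seq_len(n_rec * npr), drop = FALSE], 1, max)
  flat <- pmax - pmin < 1e-12
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeBin(charToRaw(edf_pad(x, w)), con)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8); wr("", 44)
  wr(n_rec, 8); wr(edf_num(record_duration), 8); wr(ns, 4)
  for (lab in rec$channel_names) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in pmin) wr(edf_num(v), 8)
  for (v in pmax) wr(edf_num(v), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(npr, 8)
  for (i in seq_len(ns)) wr("", 32)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * npr + 1):(r * npr)
    dig <- round((rec$data[, idx, drop = FALSE] - (pmin - dmin * scale)) / scale)
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}
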