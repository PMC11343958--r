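# Minimal reader for European Data Format (EDF) recordings: fixed-width
# ASCII header, per-signal headers, then data records of 2-byte little-endian
# integers, rescaled to physical units from the digital/physical ranges.
# Continuous equal-rate signals only; EDF+ annotation streams are dropped.

read_edf_field <- function(con, nchars) {
  raw <- readChar(con, nchars, useBytes = TRUE)
  trimws(raw)
}

#' Read an EDF (European Data Format) file
#'
#' Parses the 256-byte main header and the per-signal headers, reads all
#' data records and rescales digital values to physical units. All retained
#' signals must share one sampling rate; signals labelled as EDF+
#' annotations are skipped.
#'
#' @param path path to the `.edf` file.
#' @return A list with `data` (channels x samples matrix, physical units),
#'   `rate_hz`, `channel_names` and `meta` (patient/recording id strings).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_edf_field(con, 8L)
  patient <- read_edf_field(con, 80L)
  rec_id <- read_edf_field(con, 80L)
  start_date <- read_edf_field(con, 8L)
  start_time <- read_edf_field(con, 8L)
  header_bytes <- as.integer(read_edf_field(con, 8L))
  read_edf_field(con, 44L)                       # reserved
  n_records <- as.integer(read_edf_field(con, 8L))
  record_dur <- as.numeric(read_edf_field(con, 8L))
  ns <- as.integer(read_edf_field(con, 4L))
  if (is.na(ns) || ns < 1L) stop("not a readable EDF file: ", path)

  labels <- vapply(seq_len(ns), function(i) read_edf_field(con, 16L), "")
  vapply(seq_len(ns), function(i) read_edf_field(con, 80L), "")  # transducer
  vapply(seq_len(ns), function(i) read_edf_field(con, 8L), "")   # phys dim
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) read_edf_field(con, 8L), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) read_edf_field(con, 8L), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) read_edf_field(con, 8L), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) read_edf_field(con, 8L), ""))
  vapply(seq_len(ns), function(i) read_edf_field(con, 80L), "")  # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) read_edf_field(con, 8L), ""))
  vapply(seq_len(ns), function(i) read_edf_field(con, 32L), "")  # reserved
  seek(con, header_bytes)

  if (is.na(n_records) || n_records < 0L) stop("EDF file has unknown record count")
  if (!is.finite(record_dur) || record_dur <= 0)
    stop("EDF record duration must be positive")

  keep <- !grepl("EDF Annotations", labels, fixed = TRUE)
  if (!any(keep)) stop("EDF file contains no signal channels")
  rates <- spr[keep] / record_dur
  if (length(unique(rates)) != 1L)
    stop("EDF signals with differing sampling rates are not supported")

  per_record <- sum(spr)
  raw <- readBin(con, "integer", n = per_record * n_records, size = 2L,
                 endian = "little", signed = TRUE)
  if (length(raw) < per_record * n_records)
    stop("EDF file truncated: expected ", per_record * n_records,
         " samples, got ", length(raw))

  offs <- c(0L, cumsum(spr))
  chans <- which(keep)
  out <- matrix(0, nrow = length(chans), ncol = spr[chans[1L]] * n_records)
  for (ci in seq_along(chans)) {
    s <- chans[ci]
    idx <- as.vector(outer(seq_len(spr[s]) + offs[s],
                           (seq_len(n_records) - 1L) * per_record, `+`))
    dig <- raw[idx]
    gain <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
    out[ci, ] <- (dig - dig_min[s]) * gain + phys_min[s]
  }
  list(data = out, rate_hz = rates[1L], channel_names = labels[keep],
       meta = list(version = version, patient = patient, recording = rec_id,
                   start_date = start_date, start_time = start_time))
}
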