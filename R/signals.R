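#' Multichannel recording container
#'
#' Bundles an m-channel x T-sample signal matrix with its sampling rate and
#' channel names. Channels are bipolar iEEG derivations in the intended use
#' (each channel the potential difference of two adjacent sensors), but any
#' real-valued multichannel series is accepted.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param rate_hz positive sampling rate in Hz.
#' @param channel_names character vector of unique channel identifiers; when
#'   missing, rownames of `data` are used.
#' @return An object of class `mc_recording` with elements `data`, `rate_hz`
#'   and `channel_names`.
#' @export
recording <- function(data, rate_hz, channel_names = rownames(data)) {
  data <- as.matrix(data)
  if (is.null(channel_names))
    stop("channel_names are required (or set rownames on data)")
  channel_names <- as.character(channel_names)
  if (nrow(data) != length(channel_names))
    stop("channel_names length must equal the number of rows of data")
  if (nrow(data) < 2L)
    stop("a recording needs at least 2 channels")
  if (ncol(data) < 1L)
    stop("a recording needs at least 1 sample")
  if (anyDuplicated(channel_names))
    stop("duplicate channel names: ",
         paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0)
    stop("rate_hz must be a single positive number")
  if (!all(is.finite(data)))
    stop("recording contains non-finite samples")
  rownames(data) <- channel_names
  structure(list(data = data, rate_hz = as.numeric(rate_hz),
                 channel_names = channel_names),
            class = "mc_recording")
}

#' @export
print.mc_recording <- function(x, ...) {
  cat(sprintf("<mc_recording> %d channels x %d samples @ %g Hz (%.3f s)\n",
              n_channels(x), n_samples(x), x$rate_hz,
              n_samples(x) / x$rate_hz))
  cat("channels:", paste(utils::head(x$channel_names, 8), collapse = ", "),
      if (n_channels(x) > 8) "..." else "", "\n")
  invisible(x)
}

#' @rdname recording
#' @param rec an `mc_recording`.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname recording
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Read a multichannel recording from disk
#'
#' Supports European Data Format (EDF) files and delimited text matrices
#' with one header row of channel names and one column per channel (rows are
#' samples). The text dialect is comma- or tab-delimited, auto-detected,
#' decimal point only. For text input the sampling rate is not stored in the
#' file and must be supplied.
#'
#' @param path path to the file.
#' @param format_hint `"auto"` (by extension), `"edf"` or `"text"`.
#' @param rate_hz sampling rate in Hz, required for text input; ignored for
#'   EDF (taken from the file header).
#' @param on_nonfinite what to do with non-finite samples after load:
#'   `"error"` rejects the file, `"impute"` replaces them by linear
#'   interpolation along time.
#' @return An [recording()] object with channel order as on disk.
#' @export
read_recording <- function(path,
                           format_hint = c("auto", "edf", "text"),
                           rate_hz = NULL,
                           on_nonfinite = c("error", "impute")) {
  format_hint <- match.arg(format_hint)
  on_nonfinite <- match.arg(on_nonfinite)
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- format_hint
  if (fmt == "auto")
    fmt <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "text"
  if (fmt == "edf") {
    parsed <- read_edf(path)
    dat <- parsed$data
    rate <- parsed$rate_hz
    nms <- parsed$channel_names
  } else {
    if (is.null(rate_hz))
      stop("rate_hz must be supplied for delimited-text recordings")
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, colClasses = "numeric")
    if (nrow(tab) < 1L || ncol(tab) < 1L) stop("empty recording file: ", path)
    nms <- colnames(tab)
    dat <- t(as.matrix(tab))
    rate <- rate_hz
  }
  if (anyDuplicated(nms))
    stop("duplicate channel names in ", path, ": ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  if (!all(is.finite(dat))) {
    if (on_nonfinite == "error")
      stop("non-finite samples in ", path,
           " (use on_nonfinite = \"impute\" to interpolate)")
    dat <- t(apply(dat, 1L, impute_linear))
  }
  recording(dat, rate, nms)
}

# linear interpolation of non-finite samples within one channel
impute_linear <- function(x) {
  bad <- !is.finite(x)
  if (!any(bad)) return(x)
  if (all(bad)) stop("channel has no finite samples to interpolate from")
  idx <- seq_along(x)
  x[bad] <- stats::approx(idx[!bad], x[!bad], xout = idx[bad], rule = 2)$y
  x
}

#' Write a recording as delimited text
#'
#' One header row of channel names, one column per channel, rows are
#' samples; the inverse of [read_recording()] for text input.
#'
#' @param rec an `mc_recording`.
#' @param path output path.
#' @param sep column separator, `","` or `"\t"`.
#' @export
write_recording <- function(rec, path, sep = ",") {
  stopifnot(inherits(rec, "mc_recording"))
  tab <- as.data.frame(t(rec$data))
  colnames(tab) <- rec$channel_names
  utils::write.table(tab, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Select (and reorder) channels of a recording
#'
#' @param rec an `mc_recording`.
#' @param names channels to keep, in the desired order.
#' @return The sub-recording.
#' @export
select_channels <- function(rec, names) {
  stopifnot(inherits(rec, "mc_recording"))
  missing <- setdiff(names, rec$channel_names)
  if (length(missing))
    stop("unknown channel(s): ", paste(missing, collapse = ", "))
  recording(rec$data[names, , drop = FALSE], rec$rate_hz, names)
}

#' Epoch scheme: named time intervals over a recording
#'
#' An ordered set of named `[start_s, end_s)` analysis intervals (epochs may
#' overlap, as the three ictal epochs do) plus the ictal phase boundaries.
#'
#' @param epochs data.frame with columns `name`, `start_s`, `end_s`.
#' @param ictal_start_s,ictal_end_s seizure phase boundaries in seconds.
#' @return An object of class `epoch_scheme`.
#' @export
epoch_scheme <- function(epochs, ictal_start_s = NA_real_,
                         ictal_end_s = NA_real_) {
  epochs <- as.data.frame(epochs)
  stopifnot(all(c("name", "start_s", "end_s") %in% names(epochs)))
  epochs$name <- as.character(epochs$name)
  epochs$start_s <- as.numeric(epochs$start_s)
  epochs$end_s <- as.numeric(epochs$end_s)
  if (any(epochs$start_s >= epochs$end_s))
    stop("every epoch must satisfy start_s < end_s")
  if (anyDuplicated(epochs$name)) stop("epoch names must be unique")
  structure(list(epochs = epochs,
                 phase_boundaries = c(ictal_start_s = as.numeric(ictal_start_s),
                                      ictal_end_s = as.numeric(ictal_end_s))),
            class = "epoch_scheme")
}

#' Read an epoch scheme from a YAML file
#'
#' Expected layout: a mapping `epochs:` of `name: [start_s, end_s]` pairs
#' (order preserved) and optionally `ictal: [start_s, end_s]`.
#'
#' @param path YAML file.
#' @return An [epoch_scheme()].
#' @export
read_epoch_scheme <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$epochs)) stop("epoch scheme file lacks an 'epochs' mapping")
  epochs <- data.frame(
    name = names(y$epochs),
    start_s = vapply(y$epochs, function(e) as.numeric(e[[1]]), 0),
    end_s = vapply(y$epochs, function(e) as.numeric(e[[2]]), 0),
    stringsAsFactors = FALSE)
  ict <- y$ictal %||% c(NA_real_, NA_real_)
  epoch_scheme(epochs, as.numeric(ict[[1]]), as.numeric(ict[[2]]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Slice a recording into its epochs
#'
#' Seconds are mapped to 0-based sample indices by `floor(s * rate)` and the
#' slice covers the half-open interval `[floor(start_s*rate),
#' floor(end_s*rate))`, so a 16-s epoch at 256 Hz always yields exactly 4096
#' samples.
#'
#' @param rec an `mc_recording`.
#' @param scheme an [epoch_scheme()].
#' @return Named list of `mc_recording` slices, one per epoch.
#' @export
segment_epochs <- function(rec, scheme) {
  stopifnot(inherits(rec, "mc_recording"), inherits(scheme, "epoch_scheme"))
  Tn <- n_samples(rec)
  out <- list()
  for (k in seq_len(nrow(scheme$epochs))) {
    e <- scheme$epochs[k, ]
    i0 <- floor(e$start_s * rec$rate_hz)   # 0-based, inclusive
    i1 <- floor(e$end_s * rec$rate_hz)     # 0-based, exclusive
    if (i0 < 0 || i1 > Tn)
      stop(sprintf("epoch '%s' [%g, %g) s is outside the %0.3f-s recording",
                   e$name, e$start_s, e$end_s, Tn / rec$rate_hz))
    out[[e$name]] <- recording(rec$data[, (i0 + 1L):i1, drop = FALSE],
                               rec$rate_hz, rec$channel_names)
  }
  out
}

#' Build next-step training windows from an epoch
#'
#' Sliding windows of `seq_len` consecutive samples with the sample
#' immediately following each window as the prediction target. With 0-based
#' window starts `k * stride`, `n = floor((T - seq_len - 1)/stride) + 1`
#' windows fit in a T-sample epoch.
#'
#' @param rec an `mc_recording` (typically one epoch slice).
#' @param seq_len window length in samples (GRU input sequence length).
#' @param stride step between consecutive window starts.
#' @return A list of class `training_batch`: `inputs` (n x seq_len x d
#'   array), `targets` (n x d matrix), `channel_names`.
#' @export
make_windows <- function(rec, seq_len, stride = 1L) {
  stopifnot(inherits(rec, "mc_recording"))
  seq_len <- as.integer(seq_len); stride <- as.integer(stride)
  stopifnot(seq_len >= 1L, stride >= 1L)
  Tn <- n_samples(rec)
  if (Tn <= seq_len)
    stop(sprintf("epoch too short: %d samples for seq_len %d (need > seq_len)",
                 Tn, seq_len))
  n <- (Tn - seq_len - 1L) %/% stride + 1L
  d <- n_channels(rec)
  x <- t(rec$data)                        # T x d
  starts <- (seq_len(n) - 1L) * stride    # 0-based
  inputs <- array(0, dim = c(n, seq_len, d),
                  dimnames = list(NULL, NULL, rec$channel_names))
  for (t in seq_len(seq_len))
    inputs[, t, ] <- x[starts + t, , drop = FALSE]
  targets <- x[starts + seq_len + 1L, , drop = FALSE]
  colnames(targets) <- rec$channel_names
  structure(list(inputs = inputs, targets = targets,
                 channel_names = rec$channel_names),
            class = "training_batch")
}

#' Per-channel z-scoring
#'
#' Centers and scales every channel to mean 0, sd 1 (computed on the given
#' slice). Constant channels are left centered but unscaled.
#'
#' @param rec an `mc_recording`.
#' @return The standardized recording.
#' @export
zscore_channels <- function(rec) {
  stopifnot(inherits(rec, "mc_recording"))
  d <- rec$data
  mu <- rowMeans(d)
  s <- apply(d, 1L, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  recording((d - mu) / s, rec$rate_hz, rec$channel_names)
}
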