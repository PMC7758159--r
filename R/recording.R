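# Recording container and delimited-text I/O.

#' Construct a multichannel recording
#'
#' A `recording` holds uniformly sampled channels (nerve channels in
#' microvolts after removal of the amplifier gain, blood pressure in mmHg),
#' the sampling rate, the absolute start time, and interval annotations
#' (e.g. the post-mortem segment used for noise-floor estimation). All
#' annotation times are seconds relative to the start of the recording, and
#' all intervals throughout the package are half-open `[start, end)`.
#'
#' @param channels Named list of equal-length numeric vectors.
#' @param fs Sampling rate in Hz.
#' @param t0 Absolute start time in seconds (bookkeeping only); default 0.
#' @param units Named character vector of per-channel units; defaults to
#'   `"uV"` for every channel.
#' @param annotations Data frame with columns `label`, `t_start`, `t_end`
#'   (seconds relative to the recording start), or `NULL`.
#' @return An object of class `recording`.
#' @export
recording <- function(channels, fs, t0 = 0, units = NULL, annotations = NULL) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(names(channels) == ""))
    stop("`channels` must be a non-empty named list", call. = FALSE)
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop("all channels must have the same length", call. = FALSE)
  if (lens[[1]] < 1L) stop("recording must contain at least one sample",
                           call. = FALSE)
  if (!(is.numeric(fs) && length(fs) == 1L && fs > 0))
    stop("`fs` must be a positive number", call. = FALSE)
  if (is.null(units)) {
    units <- rep("uV", length(channels))
    names(units) <- names(channels)
  }
  annotations <- validate_annotations(annotations, lens[[1]] / fs)
  structure(list(channels = lapply(channels, as.numeric), fs = fs, t0 = t0,
                 units = units, annotations = annotations),
            class = "recording")
}

#' Create an annotation table
#'
#' @param label Character labels (e.g. `"postmortem"`, `"stim_window"`).
#' @param t_start,t_end Interval bounds in seconds relative to the start of
#'   the recording; half-open `[t_start, t_end)`.
#' @return A data frame usable as the `annotations` field of [recording()].
#' @export
annotation <- function(label, t_start, t_end) {
  data.frame(label = as.character(label), t_start = as.numeric(t_start),
             t_end = as.numeric(t_end), stringsAsFactors = FALSE)
}

validate_annotations <- function(ann, duration) {
  if (is.null(ann)) {
    return(data.frame(label = character(), t_start = numeric(),
                      t_end = numeric(), stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(ann),
            all(c("label", "t_start", "t_end") %in% names(ann)))
  ann <- ann[, c("label", "t_start", "t_end")]
  bad <- ann$t_start < 0 | ann$t_start >= ann$t_end |
    ann$t_end > duration + 1e-9
  if (any(bad))
    stop("annotations must satisfy 0 <= t_start < t_end <= duration",
         call. = FALSE)
  ann
}

#' @export
print.recording <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              length(x$channels), n, x$fs, n / x$fs))
  cat("  channels:", paste(sprintf("%s [%s]", names(x$channels), x$units),
                           collapse = ", "), "\n")
  if (nrow(x$annotations))
    cat("  annotations:",
        paste(sprintf("%s [%g, %g)", x$annotations$label,
                      x$annotations$t_start, x$annotations$t_end),
              collapse = "; "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec A [recording()].
#' @return Duration in seconds.
#' @export
rec_duration <- function(rec) length(rec$channels[[1]]) / rec$fs

annotation_path <- function(path) {
  paste0(sub("\\.[^./\\\\]*$", "", path), ".annotations.csv")
}

#' Read a recording from delimited text
#'
#' Expects a header row, a `time` column in seconds and one column per
#' channel. The time column must advance at a constant step consistent with
#' `fs` to within 1 ppm. If `gain` is given, signal columns are divided by
#' it (e.g. `gain = 10000` converts raw amplifier output back to the
#' electrode-referred signal in microvolts). A sidecar annotation file
#' `<stem>.annotations.csv` (columns `label,t_start,t_end`) is loaded when
#' present.
#'
#' @param path Path to a delimited text file.
#' @param fs Expected sampling rate in Hz; if `NULL`, inferred from the time
#'   column.
#' @param gain Amplifier gain to divide out of every non-time column;
#'   default 1.
#' @return A [recording()].
#' @export
read_recording <- function(path, fs = NULL, gain = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, data.table = FALSE)
  if (nrow(dt) == 0L) stop("empty recording file: ", path, call. = FALSE)
  if (!"time" %in% names(dt))
    stop("malformed input: no `time` column in ", path, call. = FALSE)
  if (ncol(dt) < 2L)
    stop("malformed input: no signal columns in ", path, call. = FALSE)
  tm <- dt$time
  if (nrow(dt) > 1L) {
    steps <- diff(tm)
    step <- stats::median(steps)
    if (step <= 0 || any(abs(steps - step) > 1e-6 * step))
      stop("malformed input: irregular time steps in ", path, call. = FALSE)
    fs_obs <- 1 / step
    if (is.null(fs)) fs <- fs_obs
    else if (abs(fs_obs - fs) > 1e-6 * fs)
      stop("malformed input: time step inconsistent with fs = ", fs,
           call. = FALSE)
  } else if (is.null(fs)) {
    stop("`fs` required for a single-sample file", call. = FALSE)
  }
  chans <- lapply(dt[setdiff(names(dt), "time")],
                  function(v) as.numeric(v) / gain)
  ann <- NULL
  apath <- annotation_path(path)
  if (file.exists(apath)) {
    ann <- data.table::fread(apath, data.table = FALSE)
  }
  recording(chans, fs = fs, t0 = tm[1], annotations = ann)
}

#' Write a recording to delimited text
#'
#' Writes a CSV with a `time` column and one column per channel, plus a
#' sidecar `<stem>.annotations.csv` when the recording carries annotations.
#' Values are written with enough digits for a lossless round trip at
#' double precision.
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  n <- length(rec$channels[[1]])
  df <- data.frame(time = rec$t0 + (seq_len(n) - 1) / rec$fs)
  for (nm in names(rec$channels)) df[[nm]] <- rec$channels[[nm]]
  ok <- tryCatch({
    data.table::fwrite(df, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write recording to ", path, call. = FALSE)
  if (nrow(rec$annotations))
    data.table::fwrite(rec$annotations, annotation_path(path))
  invisible(path)
}

#' Extract a time slice of a recording
#'
#' Times are seconds relative to the start of `rec`; the slice covers the
#' half-open interval `[t_start, t_end)` and contains exactly
#' `round((t_end - t_start) * fs)` samples. Annotations are clipped to the
#' window and re-referenced to the new start; the absolute start time `t0`
#' is advanced accordingly.
#'
#' @param rec A [recording()].
#' @param t_start,t_end Window bounds in seconds relative to the recording
#'   start.
#' @return A [recording()].
#' @export
slice_recording <- function(rec, t_start, t_end) {
  dur <- rec_duration(rec)
  if (!(t_start >= 0 && t_start < t_end && t_end <= dur + 1e-9))
    stop("slice window [", t_start, ", ", t_end,
         ") outside recording of duration ", dur, call. = FALSE)
  i0 <- round(t_start * rec$fs)
  nn <- round((t_end - t_start) * rec$fs)
  idx <- (i0 + 1L):(i0 + nn)
  ann <- rec$annotations
  if (nrow(ann)) {
    ann$t_start <- pmax(ann$t_start, t_start) - t_start
    ann$t_end <- pmin(ann$t_end, t_end) - t_start
    ann <- ann[ann$t_start < ann$t_end, , drop = FALSE]
    row.names(ann) <- NULL
  }
  recording(lapply(rec$channels, function(v) v[idx]), fs = rec$fs,
            t0 = rec$t0 + t_start, units = rec$units, annotations = ann)
}

#' Fetch one channel of a recording
#' @param rec A [recording()].
#' @param channel Channel name; defaults to the first channel.
#' @return Numeric sample vector.
#' @export
rec_channel <- function(rec, channel = NULL) {
  if (is.null(channel)) return(rec$channels[[1]])
  if (!channel %in% names(rec$channels))
    stop("no channel named `", channel, "`", call. = FALSE)
  rec$channels[[channel]]
}

#' Look up an annotation by label
#' @param rec A [recording()].
#' @param label Annotation label to find.
#' @return One-row data frame (`label`, `t_start`, `t_end`).
#' @export
get_annotation <- function(rec, label) {
  hit <- rec$annotations[rec$annotations$label == label, , drop = FALSE]
  if (nrow(hit) == 0L)
    stop("recording has no annotation labelled `", label, "`", call. = FALSE)
  hit[1L, , drop = FALSE]
}
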