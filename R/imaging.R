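# Stained-area quantification: 8-bit intensity histograms, intermodes
# thresholding and area fractions, averaged per animal over fields of view.

#' 8-bit intensity histogram of a grayscale image
#'
#' Float images are quantized to 0..255 by linear min-max scaling (a
#' constant image maps to level 0). Integer images already in 0..255 are
#' histogrammed as is.
#'
#' @param image Numeric matrix.
#' @return List of class `intensity_histogram` with `counts` (length 256,
#'   levels 0..255) and `quantized` (integer matrix of pixel levels).
#' @export
intensity_histogram <- function(image) {
  if (!is.matrix(image) || length(image) == 0L)
    stop("`image` must be a non-empty matrix", call. = FALSE)
  v <- as.numeric(image)
  lo <- min(v); hi <- max(v)
  if (all(v == round(v)) && lo >= 0 && hi <= 255) {
    q <- matrix(as.integer(v), nrow(image), ncol(image))
  } else if (hi > lo) {
    q <- matrix(as.integer(floor((v - lo) / (hi - lo) * 255 + 0.5)),
                nrow(image), ncol(image))
  } else {
    q <- matrix(0L, nrow(image), ncol(image))
  }
  structure(list(counts = tabulate(as.vector(q) + 1L, nbins = 256L),
                 quantized = q),
            class = "intensity_histogram")
}

# one smoothing pass: 3-bin mean with zeros outside the histogram support
smooth3 <- function(h) {
  n <- length(h)
  (c(0, h[-n]) + h + c(h[-1], 0)) / 3
}

count_modes <- function(h) {
  # strict rise then strict fall; plateaus count once
  change <- which(diff(h) != 0)
  run_start <- c(1L, change + 1L)
  y <- h[run_start]
  m <- length(y)
  if (m < 3L) return(if (m >= 1L && which.max(y) > 0) 1L else 0L)
  core <- 2:(m - 1L)
  sum(y[core] > y[core - 1L] & y[core] > y[core + 1L]) +
    (y[1] > y[2]) + (y[m] > y[m - 1L])
}

mode_bins <- function(h) {
  change <- which(diff(h) != 0)
  run_start <- c(1L, change + 1L)
  y <- h[run_start]
  m <- length(y)
  core <- 2:(m - 1L)
  pk <- run_start[core][y[core] > y[core - 1L] & y[core] > y[core + 1L]]
  if (y[1] > y[2]) pk <- c(run_start[1], pk)
  if (y[m] > y[m - 1L]) pk <- c(pk, run_start[m])
  sort(pk)
}

#' Intermodes threshold of an intensity histogram
#'
#' The histogram is repeatedly smoothed with a running 3-bin mean until
#' exactly two local maxima survive; the threshold is the integer midpoint
#' `floor((j + k) / 2)` of the two surviving mode levels. Histograms that
#' never become bimodal within the iteration cap (e.g. strictly unimodal
#' ones) raise an error.
#'
#' @param h An [intensity_histogram()], or a numeric vector of counts
#'   (levels assumed 0-based).
#' @param max_iter Smoothing iteration cap; default 10000.
#' @return Integer threshold level (same 0-based scale as the histogram).
#' @export
intermodes_threshold <- function(h, max_iter = 10000L) {
  counts <- if (inherits(h, "intensity_histogram")) h$counts else
    as.numeric(h)
  if (sum(counts) <= 0) stop("empty histogram", call. = FALSE)
  sm <- counts
  for (it in seq_len(max_iter)) {
    nm <- count_modes(sm)
    if (nm == 2L) {
      mb <- mode_bins(sm)
      return(as.integer(floor((mb[1] + mb[2]) / 2)) - 1L)
    }
    if (nm < 2L)
      stop("histogram is not bimodal: intermodes threshold undefined",
           call. = FALSE)
    sm <- smooth3(sm)
  }
  stop("histogram did not become bimodal within ", max_iter,
       " smoothing iterations", call. = FALSE)
}

#' Fraction of pixels above a threshold
#'
#' @param image Numeric or integer matrix (same intensity scale as `thr`;
#'   use the `quantized` matrix of [intensity_histogram()] together with an
#'   [intermodes_threshold()] level).
#' @param thr Threshold; pixels strictly above it count as stained.
#' @return Fraction in \[0, 1\].
#' @export
area_fraction <- function(image, thr) {
  if (length(image) == 0L) stop("empty image", call. = FALSE)
  mean(image > thr)
}

#' Average field-of-view fractions into one per-animal value
#'
#' Stained-area fractions are measured on several fields of view per animal
#' and reported as their arithmetic mean.
#'
#' @param fractions Numeric vector of per-field fractions (length >= 1).
#' @return Mean fraction.
#' @export
per_animal_average <- function(fractions) {
  if (length(fractions) == 0L)
    stop("no field-of-view fractions given", call. = FALSE)
  mean(as.numeric(fractions))
}

#' Quantify stained area of one image by intermodes thresholding
#'
#' Convenience wrapper: quantize, threshold with [intermodes_threshold()],
#' return the fraction of pixels above the threshold.
#'
#' @param image Numeric matrix.
#' @return List with `threshold` (0-based level) and `fraction`.
#' @export
quantify_stained_area <- function(image) {
  ih <- intensity_histogram(image)
  thr <- intermodes_threshold(ih)
  list(threshold = thr, fraction = area_fraction(ih$quantized, thr))
}
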