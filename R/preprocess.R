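# XIC extraction, elution-profile containers and peak-interval detection.

#' Construct an elution profile
#'
#' A time-ordered intensity trace for one ion species.
#'
#' @param times Retention times in seconds, strictly increasing.
#' @param intensities Non-negative ion counts, same length as `times`.
#' @return An object of class `elution_profile`.
#' @export
elution_profile <- function(times, intensities) {
  times <- as.numeric(times)
  intensities <- as.numeric(intensities)
  if (length(times) < 1L || length(times) != length(intensities)) {
    stop("times and intensities must be equal-length, non-empty")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and non-negative")
  }
  structure(list(times = times, intensities = intensities),
            class = "elution_profile")
}

#' @export
length.elution_profile <- function(x) length(x$times)

#' @export
print.elution_profile <- function(x, ...) {
  cat(sprintf("<elution_profile> %d scans, rt %.1f-%.1f s, apex %.3g\n",
              length(x$times), min(x$times), max(x$times),
              max(x$intensities)))
  invisible(x)
}

#' Construct a 12C/13C isotope pair
#'
#' The paired monoisotopic (y1) and first-heavy-isotope (y2) elution profiles
#' of one identified peptide, on a shared time grid, together with the
#' peptide's theoretical isotope intensity ratio r = x2/x1.
#'
#' @param y1,y2 `elution_profile` objects on identical time grids; y1 is the
#'   monoisotopic (taller) species.
#' @param r Theoretical isotope ratio in (0, 1).
#' @param peptide List or one-row data frame with at least `sequence` and
#'   `charge`.
#' @param interval Optional `peak_interval` on the shared grid.
#' @return An object of class `isotope_pair`.
#' @export
isotope_pair <- function(y1, y2, r, peptide = NULL, interval = NULL) {
  stopifnot(inherits(y1, "elution_profile"), inherits(y2, "elution_profile"))
  if (!isTRUE(all.equal(y1$times, y2$times))) {
    stop("y1 and y2 must share one time grid")
  }
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r >= 1) {
    stop("isotope ratio r must lie in (0, 1)")
  }
  structure(list(y1 = y1, y2 = y2, r = r, peptide = peptide,
                 interval = interval),
            class = "isotope_pair")
}

#' Construct a peak interval
#'
#' Half-open index interval `[start, end)` on a profile's scan axis
#' (1-based; scans `start .. end-1` lie inside the peak).
#'
#' @param start,end Integer scan indices, `1 <= start < end`.
#' @return An object of class `peak_interval`.
#' @export
peak_interval <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end <= start) {
    stop("require 1 <= start < end")
  }
  structure(list(start = start, end = end), class = "peak_interval")
}

#' Extracted ion chromatogram
#'
#' For each MS1 scan, sums the intensities of all peaks within a ppm window
#' around a target m/z. The full scan range is retained, so profiles from one
#' run share the run's time grid.
#'
#' @param scans A `scan_collection` from [read_mzxml()].
#' @param mz Target m/z in Thomson.
#' @param tol_ppm Half-width of the matching window in parts per million
#'   (default 10).
#' @return An `elution_profile` with one point per MS1 scan.
#' @export
extract_xic <- function(scans, mz, tol_ppm = 10) {
  stopifnot(inherits(scans, "scan_collection"), tol_ppm > 0, mz > 0)
  if (length(scans$times) == 0L) stop("empty scan collection")
  tol <- mz * tol_ppm * 1e-6
  ints <- vapply(seq_along(scans$times), function(i) {
    pm <- scans$mz[[i]]
    sel <- abs(pm - mz) <= tol
    if (any(sel)) sum(scans$intensity[[i]][sel]) else 0
  }, numeric(1))
  elution_profile(scans$times, ints)
}

#' Detect the elution-peak interval of a profile
#'
#' Locates the apex as the maximum of a 3-point moving average (zero-padded
#' at the edges) of the profile within `rt_window` seconds of a retention
#' time hint, then expands left and right while the smoothed intensity stays
#' at or above `boundary_frac` times the apex intensity and above zero.
#'
#' @param profile An `elution_profile` with at least 3 scans.
#' @param rt_hint Expected elution time in seconds (e.g. from the
#'   identification).
#' @param rt_window Half-width of the apex search window in seconds
#'   (default 120).
#' @param boundary_frac Fraction of the apex intensity at which the peak
#'   boundary is drawn (default 0.05).
#' @return A `peak_interval` containing the apex.
#' @export
detect_peak_interval <- function(profile, rt_hint, rt_window = 120,
                                 boundary_frac = 0.05) {
  stopifnot(inherits(profile, "elution_profile"))
  n <- length(profile)
  if (n < 3L) stop("profile too short for peak detection (need >= 3 scans)")
  y <- profile$intensities
  sm <- .movavg3(y)
  in_win <- which(abs(profile$times - rt_hint) <= rt_window)
  if (length(in_win) == 0L) stop("no scans within rt_window of rt_hint")
  apex <- in_win[which.max(sm[in_win])]
  if (y[apex] <= 0 || sm[apex] <= 0) {
    stop("no peak: zero intensity throughout the search window")
  }
  thr <- boundary_frac * y[apex]
  lo <- apex
  while (lo > 1L && sm[lo - 1L] >= thr && sm[lo - 1L] > 0) lo <- lo - 1L
  hi <- apex
  while (hi < n && sm[hi + 1L] >= thr && sm[hi + 1L] > 0) hi <- hi + 1L
  peak_interval(lo, hi + 1L)
}

.movavg3 <- function(y) {
  n <- length(y)
  pad <- c(0, y, 0)
  (pad[1:n] + pad[2:(n + 1L)] + pad[3:(n + 2L)]) / 3
}

#' Integrated abundance of a profile over a peak interval
#'
#' Trapezoidal integral of intensity over retention time, restricted to the
#' scans inside a half-open peak interval.
#'
#' @param profile An `elution_profile`.
#' @param interval A `peak_interval`; defaults to the full profile.
#' @return Integrated ion counts (counts x seconds).
#' @export
profile_area <- function(profile, interval = NULL) {
  stopifnot(inherits(profile, "elution_profile"))
  if (is.null(interval)) interval <- peak_interval(1L, length(profile) + 1L)
  stopifnot(inherits(interval, "peak_interval"))
  if (interval$end > length(profile) + 1L) stop("interval exceeds profile")
  idx <- interval$start:(interval$end - 1L)
  if (length(idx) < 2L) return(0)
  t <- profile$times[idx]
  y <- profile$intensities[idx]
  sum(diff(t) * (head(y, -1L) + tail(y, -1L)) / 2)
}

#' Apex (maximum) intensity of a profile
#'
#' @param profile An `elution_profile`.
#' @param interval Optional `peak_interval` restriction.
#' @return Maximum intensity.
#' @export
profile_apex <- function(profile, interval = NULL) {
  y <- profile$intensities
  if (!is.null(interval)) y <- y[interval$start:(interval$end - 1L)]
  max(y)
}
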