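# Correctability conditions and the iterative conditional-mode (ICM)
# estimation of the monotone correction function f (inverse: distortion g).
#
# f maps observed to true intensity. Suppression only attenuates, so
# f(y) >= y below the distortion-free threshold and f is the identity above
# it. f is represented as a monotone piecewise-linear map in log10-intensity
# with knots at data quantiles; the inverse therefore exists in closed form.

#' Configuration for correction-function estimation
#'
#' @param ratio_low,ratio_high Admissible range of the theoretical isotope
#'   ratio r; outside it the suppression is not identifiable from the pair
#'   (default 0.2-0.8).
#' @param identity_threshold Distortion-free lower limit in ion counts:
#'   observed intensity at or above it is taken as true (default 1e6).
#' @param n_knots Number of interior knots of the piecewise-linear map
#'   (default 8).
#' @param tol Convergence tolerance on the relative change of total corrected
#'   ion count between ICM iterations (default 1e-4).
#' @param max_iter Maximum ICM iterations (default 500).
#' @param ratio_tol Relative tolerance on the corrected x2/x1 area ratio
#'   versus r at convergence; exceeding it raises a warning (default 0.05).
#' @return A list of class `correction_config`.
#' @export
correction_config <- function(ratio_low = 0.2, ratio_high = 0.8,
                              identity_threshold = 1e6, n_knots = 8,
                              tol = 1e-4, max_iter = 500, ratio_tol = 0.05) {
  stopifnot(0 < ratio_low, ratio_low < ratio_high, ratio_high < 1,
            identity_threshold > 0, n_knots >= 2, tol > 0, max_iter >= 1)
  structure(list(ratio_low = ratio_low, ratio_high = ratio_high,
                 identity_threshold = identity_threshold, n_knots = n_knots,
                 tol = tol, max_iter = max_iter, ratio_tol = ratio_tol),
            class = "correction_config")
}

#' Construct a correction function
#'
#' A monotone piecewise-linear map from observed to true intensity,
#' interpolated in log10 space, equal to the identity at and above
#' `identity_threshold`. The last knot is pinned at the threshold.
#'
#' @param knots_observed,knots_true Strictly increasing intensities; the map
#'   sends `knots_observed[k]` to `knots_true[k]`, with
#'   `knots_true >= knots_observed` (suppression only attenuates observed
#'   signal).
#' @param identity_threshold Distortion-free lower limit in ion counts.
#' @return An object of class `correction_function`.
#' @export
correction_function <- function(knots_observed, knots_true,
                                identity_threshold = 1e6) {
  stopifnot(length(knots_observed) == length(knots_true),
            length(knots_observed) >= 1L,
            all(knots_observed > 0), all(knots_true > 0),
            identity_threshold > 0)
  o <- order(knots_observed)
  ko <- as.numeric(knots_observed[o]); kt <- as.numeric(knots_true[o])
  if (ko[length(ko)] < identity_threshold) {
    ko <- c(ko, identity_threshold); kt <- c(kt, identity_threshold)
  }
  keep <- ko <= identity_threshold
  ko <- ko[keep]; kt <- kt[keep]
  kt[length(kt)] <- identity_threshold  # pin identity at the threshold
  if (any(diff(log10(ko)) <= 0) || any(diff(log10(kt)) <= 0)) {
    stop("knots must be strictly increasing in both coordinates")
  }
  if (any(kt < ko * (1 - 1e-12))) {
    stop("correction must not decrease intensity: knots_true >= knots_observed")
  }
  structure(list(lko = log10(ko), lkt = log10(kt),
                 identity_threshold = identity_threshold,
                 valid_range = c(ko[1], ko[length(ko)])),
            class = "correction_function")
}

#' Identity correction function
#'
#' @param identity_threshold Distortion-free lower limit in ion counts.
#' @param span Decades below the threshold covered by the knot range
#'   (default 4).
#' @return A `correction_function` equal to the identity everywhere.
#' @export
identity_correction <- function(identity_threshold = 1e6, span = 4) {
  k <- identity_threshold * 10^c(-span, 0)
  correction_function(k, k, identity_threshold)
}

#' @export
print.correction_function <- function(x, ...) {
  cat(sprintf(
    "<correction_function> %d knots on [%.3g, %.3g], identity above %.3g\n",
    length(x$lko), x$valid_range[1], x$valid_range[2], x$identity_threshold))
  invisible(x)
}

#' Evaluate a correction function (observed -> true intensity)
#'
#' Values at or above the identity threshold map to themselves; values below
#' the lowest knot are mapped by extrapolating the lowest log-log segment;
#' zeros map to zero. Output never falls below input.
#'
#' @param f A `correction_function`.
#' @param y Observed intensities (non-negative).
#' @return Corrected intensities, same length.
#' @export
correct_intensity <- function(f, y) {
  .pwl_eval(f$lko, f$lkt, f$identity_threshold, y, lower_bound_input = TRUE)
}

#' Evaluate the distortion function (true -> observed intensity)
#'
#' The inverse of [correct_intensity()]: the knot coordinates are swapped.
#' Output never exceeds input (suppression only attenuates).
#'
#' @param f A `correction_function`.
#' @param x True intensities (non-negative).
#' @return Distorted (observed-scale) intensities.
#' @export
distort_intensity <- function(f, x) {
  .pwl_eval(f$lkt, f$lko, f$identity_threshold, x, lower_bound_input = FALSE)
}

# Piecewise-linear evaluation in log10 space with identity above the
# threshold, first-segment extrapolation below the lowest knot, and a bound
# keeping the output on the correct side of the identity line. The
# extrapolation slope is clamped to [0.1, 10]: isotonic fits can contain
# tie-broken near-flat segments whose reciprocal would send everything
# below the knot range to zero (or infinity) in one step.
.pwl_eval <- function(lkx, lky, threshold, v, lower_bound_input) {
  out <- v
  pos <- which(v > 0 & v < threshold)
  if (length(pos)) {
    lv <- log10(v[pos])
    n <- length(lkx)
    if (n == 1L) {
      lo <- lv + (lky[1] - lkx[1])
    } else {
      lo <- stats::approx(lkx, lky, xout = lv, rule = 2)$y
      below <- lv < lkx[1]
      if (any(below)) {
        s <- (lky[2] - lky[1]) / (lkx[2] - lkx[1])
        s <- min(max(s, 0.1), 10)
        lo[below] <- lky[1] + s * (lv[below] - lkx[1])
      }
    }
    out[pos] <- 10^lo
    out[pos] <- if (lower_bound_input) pmax(out[pos], v[pos])
                else pmin(out[pos], v[pos])
  }
  out
}

#' Apply a correction function to an elution profile
#'
#' @param profile An `elution_profile` of observed intensities.
#' @param f A `correction_function`.
#' @return An `elution_profile` of corrected intensities on the same time
#'   grid; pointwise no smaller than the input.
#' @export
apply_correction <- function(profile, f) {
  stopifnot(inherits(profile, "elution_profile"),
            inherits(f, "correction_function"))
  elution_profile(profile$times, correct_intensity(f, profile$intensities))
}

#' Apply a distortion function to an elution profile
#'
#' @param profile An `elution_profile` of true-scale intensities.
#' @param f A `correction_function` whose inverse supplies the distortion.
#' @return An `elution_profile` of distorted intensities.
#' @export
apply_distortion <- function(profile, f) {
  stopifnot(inherits(profile, "elution_profile"),
            inherits(f, "correction_function"))
  elution_profile(profile$times, distort_intensity(f, profile$intensities))
}

#' Check the correction conditions for an isotope pair
#'
#' A pair is correctable when its theoretical isotope ratio is away from 0
#' and 1 (otherwise suppression is not identifiable by comparing y1 and y2)
#' and the heavy-isotope profile reaches above the distortion-free lower
#' limit (otherwise the correction function cannot be estimated over the
#' range that needs correcting).
#'
#' @param pair An `isotope_pair`.
#' @param ratio_low,ratio_high Admissible ratio window (default 0.2-0.8).
#' @param threshold Distortion-free lower limit in ion counts (default 1e6).
#' @return A list of class `correctability_verdict` with elements
#'   `correctable` (logical) and `reason` (one of `"ok"`,
#'   `"ratio_out_of_range"`, `"below_intensity_limit"`).
#' @export
check_correction_conditions <- function(pair, ratio_low = 0.2,
                                        ratio_high = 0.8, threshold = 1e6) {
  stopifnot(inherits(pair, "isotope_pair"),
            0 < ratio_low, ratio_low < ratio_high, ratio_high < 1,
            threshold > 0)
  reason <- if (pair$r < ratio_low || pair$r > ratio_high) {
    "ratio_out_of_range"
  } else if (max(pair$y2$intensities) <= threshold) {
    "below_intensity_limit"
  } else "ok"
  structure(list(correctable = reason == "ok", reason = reason),
            class = "correctability_verdict")
}

#' Estimate the correction function of an isotope pair by ICM
#'
#' Iterative conditional modes: starting from the observed total ion count
#' `T = y1 + y2`, the theoretical isotope ratio r splits T into target true
#' profiles `x1* = T/(1+r)` and `x2* = r T/(1+r)`; the most probable
#' monotone correction function f is fit to the pooled observed-vs-target
#' points by weighted isotonic regression in log10 space (identity enforced
#' above the distortion-free threshold); the profiles are corrected,
#' `T = f(y1) + f(y2)` is updated, and the cycle repeats until the total
#' corrected ion count stabilises.
#'
#' @param pair An `isotope_pair` that passes
#'   [check_correction_conditions()]; its `interval` (or the full profile)
#'   defines the fitting support.
#' @param config A [correction_config()].
#' @return A list with elements `f` (`correction_function`), `x1`, `x2`
#'   (corrected `elution_profile`s on the full grid), `iterations`, `delta`
#'   (final relative change), `deltas` (per-iteration history) and
#'   `area_ratio` (corrected x2/x1 area ratio over the interval).
#' @export
fit_correction_function <- function(pair, config = correction_config()) {
  stopifnot(inherits(pair, "isotope_pair"),
            inherits(config, "correction_config"))
  verdict <- check_correction_conditions(pair, config$ratio_low,
                                         config$ratio_high,
                                         config$identity_threshold)
  if (!verdict$correctable) {
    stop(sprintf("pair fails correction conditions: %s", verdict$reason))
  }
  interval <- pair$interval
  if (is.null(interval)) interval <- peak_interval(1L, length(pair$y1) + 1L)
  idx <- interval$start:(interval$end - 1L)
  y1 <- pair$y1$intensities[idx]
  y2 <- pair$y2$intensities[idx]
  use <- y1 > 0 & y2 > 0
  if (sum(use) <= 2L) {
    stop("degenerate peak: fewer than 3 scans with signal in the interval")
  }
  y1 <- y1[use]; y2 <- y2[use]
  r <- pair$r
  thr <- config$identity_threshold
  lthr <- log10(thr)

  f <- identity_correction(thr)
  total <- sum(y1 + y2)
  delta <- Inf
  deltas <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Tt <- correct_intensity(f, y1) + correct_intensity(f, y2)
    x1t <- Tt / (1 + r)
    x2t <- r * Tt / (1 + r)
    yo <- c(y1, y2)
    xt <- pmax(c(x1t, x2t), yo)       # correction only increases intensity
    sub <- yo < thr & yo > 0
    if (!any(sub)) { f <- identity_correction(thr); break }
    u <- log10(yo[sub])
    v <- pmin(log10(xt[sub]), lthr)   # monotone + identity at threshold
    w <- xt[sub]
    # anchor continuity at the distortion-free threshold
    u <- c(u, lthr); v <- c(v, lthr); w <- c(w, max(w) * 4)
    fit <- .weighted_pava(u, v, w)
    f <- .knots_from_fit(fit$x, fit$y, config$n_knots, thr)
    new_total <- sum(correct_intensity(f, y1) + correct_intensity(f, y2))
    delta <- abs(new_total - total) / total
    deltas <- c(deltas, delta)
    total <- new_total
    if (delta < config$tol) break
    if (iter >= config$max_iter) {
      stop(sprintf(
        "ICM did not converge in %d iterations (last relative change %.3g)",
        config$max_iter, delta))
    }
  }

  x1 <- apply_correction(pair$y1, f)
  x2 <- apply_correction(pair$y2, f)
  a1 <- profile_area(x1, interval)
  a2 <- profile_area(x2, interval)
  area_ratio <- a2 / a1
  if (abs(area_ratio - r) / r > config$ratio_tol) {
    warning(sprintf(
      "corrected area ratio %.4f deviates from r = %.4f by more than %.1f%%",
      area_ratio, r, 100 * config$ratio_tol))
  }
  list(f = f, x1 = x1, x2 = x2, iterations = iter, delta = delta,
       deltas = deltas, area_ratio = area_ratio)
}

# Weighted isotonic (non-decreasing) least squares by pool-adjacent
# violators; duplicated x are merged by weighted mean first. Returns the
# fitted monotone values at the unique sorted x.
.weighted_pava <- function(x, y, w) {
  o <- order(x)
  x <- x[o]; y <- y[o]; w <- w[o]
  grp <- cumsum(c(TRUE, diff(x) > 1e-12))
  ux <- as.numeric(tapply(x, grp, function(v) v[1]))
  wy <- as.numeric(tapply(w * y, grp, sum))
  uw <- as.numeric(tapply(w, grp, sum))
  uy <- wy / uw
  n <- length(ux)
  # stack of blocks: value, weight, count
  val <- numeric(n); wt <- numeric(n); cnt <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- uy[i]; wt[top] <- uw[i]; cnt[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      val[top - 1L] <- (wt[top - 1L] * val[top - 1L] + wt[top] * val[top]) /
        (wt[top - 1L] + wt[top])
      wt[top - 1L] <- wt[top - 1L] + wt[top]
      cnt[top - 1L] <- cnt[top - 1L] + cnt[top]
      top <- top - 1L
    }
  }
  fitted <- rep.int(val[seq_len(top)], cnt[seq_len(top)])
  list(x = ux, y = fitted)
}

# Compress an isotonic fit (log10 observed -> log10 true) into a
# correction_function with knots at quantiles of the observed support.
# Flat stretches from the isotonic fit get an infinitesimal slope so the
# inverse exists.
.knots_from_fit <- function(lx, ly, n_knots, threshold) {
  lthr <- log10(threshold)
  qs <- stats::quantile(lx, probs = seq(0, 1, length.out = n_knots),
                        names = FALSE, type = 7)
  qs <- sort(unique(c(qs, lthr)))
  qs <- qs[qs <= lthr]
  lv <- stats::approx(lx, ly, xout = qs, rule = 2)$y
  lv <- pmax(lv, qs)                 # f(y) >= y
  lv <- pmin(lv, lthr)
  lv[length(lv)] <- lthr
  # strict monotonicity with an infinitesimal log-space slope for ties
  eps <- 1e-9
  keep <- c(TRUE, diff(qs) > eps)
  qs <- qs[keep]; lv <- lv[keep]
  n <- length(lv)
  if (n > 1L) {
    for (i in 2:n) if (lv[i] <= lv[i - 1L]) lv[i] <- lv[i - 1L] + eps
    if (lv[n] > lthr) {               # re-pin the threshold knot
      lv[n] <- lthr
      for (i in (n - 1L):1L) {
        if (lv[i] >= lv[i + 1L]) lv[i] <- lv[i + 1L] - eps else break
      }
    }
  }
  correction_function(10^qs, 10^lv, threshold)
}
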