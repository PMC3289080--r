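# Suppression analysis: pooling estimated correction functions, suppression
# statistics across intensity levels, experimental and predicted fold-change
# null distributions, and empirical significance of measured fold changes.

#' Construct a null distribution
#'
#' @param log_ratios Sample of log10 fold changes.
#' @param intensity_level Ion-count centre of the intensity stratum, or `NA`
#'   for the (intensity-free) experimental null.
#' @param kind One of `"experimental"`, `"predicted"`, `"observed"`.
#' @return An object of class `null_distribution`.
#' @export
null_distribution <- function(log_ratios,
                              intensity_level = NA_real_,
                              kind = c("experimental", "predicted",
                                       "observed")) {
  kind <- match.arg(kind)
  log_ratios <- as.numeric(log_ratios)
  if (any(!is.finite(log_ratios))) stop("log_ratios must be finite")
  structure(list(log_ratios = log_ratios, intensity_level = intensity_level,
                 kind = kind),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %s, n = %d, sd(log10) = %.4f%s\n",
              x$kind, length(x$log_ratios), stats::sd(x$log_ratios),
              if (is.na(x$intensity_level)) ""
              else sprintf(", level %.3g", x$intensity_level)))
  invisible(x)
}

#' Compose a function library from correction functions
#'
#' Low-level constructor; [build_function_library()] is the usual entry
#' point.
#'
#' @param functions List of `correction_function`.
#' @param provenance Character dataset label(s), recycled.
#' @return An object of class `function_library`.
#' @export
function_library <- function(functions, provenance = "manual") {
  stopifnot(length(functions) >= 1L,
            all(vapply(functions, inherits, logical(1),
                       "correction_function")))
  structure(list(functions = functions,
                 provenance = rep_len(provenance, length(functions)),
                 skipped = data.frame(peptide = character(0),
                                      reason = character(0),
                                      stringsAsFactors = FALSE)),
            class = "function_library")
}

#' Build a library of correction/distortion functions
#'
#' Fits every correctable isotope pair with [fit_correction_function()] and
#' pools the results; the fitted functions are treated as random samples of
#' all possible correction functions of the instrument run. Uncorrectable
#' pairs are skipped with their reason recorded.
#'
#' @param pairs List of `isotope_pair`.
#' @param config A [correction_config()].
#' @param provenance Optional character dataset label(s), recycled.
#' @return An object of class `function_library`: list with `functions`
#'   (list of `correction_function`), `provenance`, and `skipped` (data
#'   frame of sequence/reason for every skipped pair).
#' @export
build_function_library <- function(pairs, config = correction_config(),
                                   provenance = "dataset") {
  stopifnot(length(pairs) >= 1L)
  provenance <- rep_len(provenance, length(pairs))
  funs <- list(); prov <- character(0)
  skip_seq <- character(0); skip_reason <- character(0)
  for (i in seq_along(pairs)) {
    pair <- pairs[[i]]
    verdict <- check_correction_conditions(pair, config$ratio_low,
                                           config$ratio_high,
                                           config$identity_threshold)
    if (!verdict$correctable) {
      skip_seq <- c(skip_seq, .pair_label(pair))
      skip_reason <- c(skip_reason, verdict$reason)
      next
    }
    fit <- tryCatch(fit_correction_function(pair, config),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      skip_seq <- c(skip_seq, .pair_label(pair))
      skip_reason <- c(skip_reason, paste0("fit_failed: ",
                                           conditionMessage(fit)))
      next
    }
    funs <- c(funs, list(fit$f))
    prov <- c(prov, provenance[i])
  }
  if (length(funs) == 0L) {
    tab <- sort(table(skip_reason), decreasing = TRUE)
    stop(sprintf(
      "no correctable pairs: most frequent failure is '%s' (%d of %d pairs)",
      names(tab)[1], tab[1], length(pairs)))
  }
  structure(list(functions = funs, provenance = prov,
                 skipped = data.frame(peptide = skip_seq,
                                      reason = skip_reason,
                                      stringsAsFactors = FALSE)),
            class = "function_library")
}

.pair_label <- function(pair) {
  if (is.null(pair$peptide)) "<unnamed>"
  else sprintf("%s/%s", pair$peptide$sequence, pair$peptide$charge)
}

#' @export
print.function_library <- function(x, ...) {
  cat(sprintf("<function_library> %d functions (%d pairs skipped)\n",
              length(x$functions), nrow(x$skipped)))
  invisible(x)
}

#' @export
length.function_library <- function(x) length(x$functions)

#' Suppression statistics across intensity levels
#'
#' For each requested level the template elution profile is scaled so its
#' apex equals the level, every distortion function in the library is
#' applied, and the ratio of distorted to undistorted area summarises the
#' suppression. Mean, SD and the mean +/- 3 SD band across the library
#' describe the range of suppression at that level.
#'
#' @param library A `function_library`.
#' @param template An `elution_profile` giving the typical peak shape
#'   (default: unit Gaussian shape, SD 5 scans).
#' @param levels Apex ion counts at which to evaluate.
#' @return Data frame of class `suppression_stats` with columns `level`,
#'   `mean`, `sd`, `lo1`, `hi1`, `lo3`, `hi3`.
#' @export
suppression_statistics <- function(library, template = NULL,
                                   levels = 10^seq(4.5, 6.5, by = 0.5)) {
  stopifnot(inherits(library, "function_library"), all(levels > 0))
  if (is.null(template)) template <- default_template()
  stopifnot(inherits(template, "elution_profile"))
  shape <- template$intensities / max(template$intensities)
  rows <- lapply(levels, function(L) {
    scaled <- elution_profile(template$times, shape * L)
    base <- profile_area(scaled)
    ratios <- vapply(library$functions, function(f) {
      profile_area(apply_distortion(scaled, f)) / base
    }, numeric(1))
    m <- mean(ratios); s <- stats::sd(ratios)
    if (is.na(s)) s <- 0
    data.frame(level = L, mean = m, sd = s,
               lo1 = m - s, hi1 = m + s, lo3 = m - 3 * s, hi3 = m + 3 * s)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("suppression_stats", "data.frame")
  out
}

#' Default template elution profile
#'
#' Unit-apex Gaussian peak shape, SD 5 scans at 1 s spacing.
#'
#' @param n_scans Number of scans (default 61).
#' @param shape_sd Gaussian SD in scans (default 5).
#' @return An `elution_profile` with apex 1.
#' @export
default_template <- function(n_scans = 61, shape_sd = 5) {
  i <- seq_len(n_scans)
  elution_profile(seq(0, by = 1, length.out = n_scans),
                  exp(-0.5 * ((i - (n_scans + 1) / 2) / shape_sd)^2))
}

#' Experimental null distribution from a 1:1 replicate pair
#'
#' Matches peptides by (sequence, charge) across the two runs and records
#' the log10 ratio of integrated monoisotopic abundances for every peptide
#' whose monoisotopic apex exceeds the distortion-free threshold in both
#' runs. Those fold changes carry only experimental (sample-handling)
#' variation, not instrumental suppression.
#'
#' @param pairs_run1,pairs_run2 Lists of `isotope_pair` from the two runs of
#'   a 1:1 dataset pair.
#' @param threshold Distortion-free lower limit in ion counts (default 1e6).
#' @return A `null_distribution` of kind `"experimental"`. Fewer than 30
#'   usable peptides attaches a `small_sample` warning flag; fewer than 5 is
#'   an error.
#' @export
experimental_null <- function(pairs_run1, pairs_run2, threshold = 1e6) {
  m <- .match_pairs(pairs_run1, pairs_run2)
  lr <- numeric(0)
  for (k in seq_len(nrow(m))) {
    p1 <- pairs_run1[[m$i1[k]]]; p2 <- pairs_run2[[m$i2[k]]]
    if (profile_apex(p1$y1, p1$interval) > threshold &&
        profile_apex(p2$y1, p2$interval) > threshold) {
      a1 <- profile_area(p1$y1, p1$interval)
      a2 <- profile_area(p2$y1, p2$interval)
      if (a1 > 0 && a2 > 0) lr <- c(lr, log10(a2 / a1))
    }
  }
  if (length(lr) < 5L) {
    stop(sprintf(
      "only %d suppression-free matched peptides; need at least 5", length(lr)))
  }
  nd <- null_distribution(lr, kind = "experimental")
  if (length(lr) < 30L) {
    warning(sprintf(
      "experimental null from only %d peptides (< 30); P-values unreliable",
      length(lr)))
    attr(nd, "small_sample") <- TRUE
  }
  nd
}

.match_pairs <- function(pairs_run1, pairs_run2) {
  key <- function(ps) vapply(ps, .pair_label, character(1))
  k1 <- key(pairs_run1); k2 <- key(pairs_run2)
  common <- intersect(k1, k2)
  data.frame(key = common,
             i1 = match(common, k1), i2 = match(common, k2),
             stringsAsFactors = FALSE)
}

#' Predict the fold-change null distribution at an intensity level
#'
#' Draws fold changes a_j from the experimental null (resampling with
#' replacement), treats the scaled template y_p as a peptide profile in one
#' run and `a_j * y_p` as the matching profile in the other, pushes both
#' through every distortion function g_i in the library, and records
#' `r_ij = area(g_i(a_j y_p)) / area(g_i(y_p))`. The pooled log10 r_ij form
#' the predicted null at the level: experimental variation widened by
#' intensity-dependent suppression.
#'
#' @param exp_null A `null_distribution` of kind `"experimental"`.
#' @param library A `function_library`.
#' @param template Template `elution_profile` (default [default_template()]).
#' @param level Apex ion counts of the intensity stratum.
#' @param n_draws Draws from the experimental null (default 1000).
#' @param seed Integer seed; fixes the resampling.
#' @return A `null_distribution` of kind `"predicted"` with
#'   `length(library) * n_draws` points. If the scaled template lies
#'   entirely in the distortion-free range the experimental null is simply
#'   resampled and the result carries attribute `undistorted = TRUE`.
#' @export
predict_null <- function(exp_null, library, template = NULL, level,
                         n_draws = 1000, seed = 1) {
  stopifnot(inherits(exp_null, "null_distribution"),
            exp_null$kind == "experimental",
            inherits(library, "function_library"),
            level > 0, n_draws >= 1)
  if (is.null(template)) template <- default_template()
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  a <- 10^sample(exp_null$log_ratios, n_draws, replace = TRUE)
  shape <- template$intensities / max(template$intensities)
  yp <- shape * level
  pos <- yp > 0
  thr_max <- max(vapply(library$functions, function(f) f$identity_threshold,
                        numeric(1)))
  if (min(yp[pos]) >= thr_max && min(a * level) >= thr_max) {
    nd <- null_distribution(log10(a), intensity_level = level,
                            kind = "predicted")
    attr(nd, "undistorted") <- TRUE
    return(nd)
  }
  dt <- diff(template$times)
  area_of <- function(int_matrix) {
    # rows: draws, cols: scans; trapezoid along scans
     (int_matrix[, -ncol(int_matrix), drop = FALSE] +
    int_matrix[, -1L, drop = FALSE]) %*% (dt / 2)
  }
  lr <- vector("list", length(library$functions))
  scaled_mat <- outer(a, yp)  # n_draws x n_scans
  for (i in seq_along(library$functions)) {
    f <- library$functions[[i]]
    base <- profile_area(apply_distortion(elution_profile(template$times, yp),
                                          f))
    dist_vals <- distort_intensity(f, as.vector(scaled_mat))
    num <- area_of(matrix(dist_vals, nrow = n_draws))
    lr[[i]] <- log10(as.vector(num) / base)
  }
  null_distribution(unlist(lr), intensity_level = level, kind = "predicted")
}

#' Kolmogorov-Smirnov comparison of two null distributions
#'
#' Two-sample KS test of the log10 fold-change samples. Resampled empirical
#' nulls contain ties, so the tie warning from [stats::ks.test()] is
#' suppressed; the asymptotic p-value is returned.
#'
#' @param a,b `null_distribution` objects (or numeric samples), each with at
#'   least 5 points.
#' @return List with `D` (statistic) and `p_value`.
#' @export
ks_compare <- function(a, b) {
  xa <- if (inherits(a, "null_distribution")) a$log_ratios else as.numeric(a)
  xb <- if (inherits(b, "null_distribution")) b$log_ratios else as.numeric(b)
  stopifnot(length(xa) >= 5L, length(xb) >= 5L)
  kt <- suppressWarnings(stats::ks.test(xa, xb))
  list(D = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Empirical significance of a measured fold change
#'
#' Two-sided add-one empirical P-value: the fraction of null log-ratios at
#' least as far from the null median as the measured log fold change, with
#' the +1 correction that keeps P-values strictly positive.
#'
#' @param fc Measured fold change (> 0, dataset 2 / dataset 1).
#' @param null A `null_distribution` with at least 30 points.
#' @return P-value in (0, 1].
#' @export
fold_change_pvalue <- function(fc, null) {
  stopifnot(is.numeric(fc), fc > 0, inherits(null, "null_distribution"))
  lr <- null$log_ratios
  m <- length(lr)
  if (m < 30L) stop("null distribution has fewer than 30 points")
  med <- stats::median(lr)
  # small slack so fc values that reconstruct a null point exactly (up to
  # log/exp rounding) count that point as "at least as extreme"
  k <- sum(abs(lr - med) >= abs(log10(fc) - med) - 1e-12)
  (k + 1) / (m + 1)
}

#' Analysis configuration for significance assignment
#'
#' @param correction A [correction_config()].
#' @param threshold Distortion-free lower limit used for the suppression-free
#'   stratum (defaults to the correction config's identity threshold).
#' @param n_draws Draws per predicted null (default 1000).
#' @param seed Base seed for predicted-null resampling (default 1).
#' @param template Template profile for null prediction (default
#'   [default_template()]).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(correction = correction_config(),
                            threshold = correction$identity_threshold,
                            n_draws = 1000, seed = 1, template = NULL) {
  structure(list(correction = correction, threshold = threshold,
                 n_draws = n_draws, seed = seed,
                 template = if (is.null(template)) default_template()
                            else template),
            class = "analysis_config")
}

#' Assign fold changes and significance P-values across a run pair
#'
#' Matches peptides by (sequence, charge). Peptides correctable in both runs
#' are corrected and their fold change tested against the experimental null;
#' all others keep their observed abundances, and the P-value is computed
#' against the predicted null of the half-decade log10 intensity bin of the
#' taller profile's apex (one predicted null per bin, cached).
#'
#' @param pairs_run1,pairs_run2 Lists of `isotope_pair` for the two runs.
#' @param library A `function_library` of distortion functions for the
#'   instrument.
#' @param exp_null Experimental `null_distribution`.
#' @param config An [analysis_config()].
#' @return Data frame with one row per matched peptide: `sequence`,
#'   `charge`, per-dataset abundances before/after correction,
#'   `correctable`, `fold_change`, `p_value`, `reason` (NA unless the
#'   peptide failed), plus the intensity `bin_level` used for uncorrectable
#'   peptides.
#' @export
assign_significance <- function(pairs_run1, pairs_run2, library, exp_null,
                                config = analysis_config()) {
  stopifnot(inherits(library, "function_library"),
            inherits(exp_null, "null_distribution"),
            inherits(config, "analysis_config"))
  m <- .match_pairs(pairs_run1, pairs_run2)
  if (nrow(m) == 0L) stop("no matched peptides between the two runs")
  null_cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(m))
  for (k in seq_len(nrow(m))) {
    p1 <- pairs_run1[[m$i1[k]]]; p2 <- pairs_run2[[m$i2[k]]]
    rows[[k]] <- tryCatch(
      .score_peptide(p1, p2, library, exp_null, config, null_cache),
      error = function(e) {
        data.frame(sequence = p1$peptide$sequence, charge = p1$peptide$charge,
                   abundance_before_1 = NA_real_,
                   abundance_before_2 = NA_real_,
                   correctable = FALSE,
                   abundance_after_1 = NA_real_,
                   abundance_after_2 = NA_real_,
                   fold_change = NA_real_, p_value = NA_real_,
                   bin_level = NA_real_,
                   reason = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
  }
  do.call(rbind, rows)
}

.score_peptide <- function(p1, p2, library, exp_null, config, null_cache) {
  cc <- config$correction
  a1_before <- profile_area(p1$y1, p1$interval)
  a2_before <- profile_area(p2$y1, p2$interval)
  if (a1_before <= 0 || a2_before <= 0) stop("zero abundance in one run")
  v1 <- check_correction_conditions(p1, cc$ratio_low, cc$ratio_high,
                                    cc$identity_threshold)
  v2 <- check_correction_conditions(p2, cc$ratio_low, cc$ratio_high,
                                    cc$identity_threshold)
  if (v1$correctable && v2$correctable) {
    fit1 <- fit_correction_function(p1, cc)
    fit2 <- fit_correction_function(p2, cc)
    a1_after <- profile_area(fit1$x1, p1$interval)
    a2_after <- profile_area(fit2$x1, p2$interval)
    fc <- a2_after / a1_after
    p <- fold_change_pvalue(fc, exp_null)
    return(data.frame(
      sequence = p1$peptide$sequence, charge = p1$peptide$charge,
      abundance_before_1 = a1_before, abundance_before_2 = a2_before,
      correctable = TRUE,
      abundance_after_1 = a1_after, abundance_after_2 = a2_after,
      fold_change = fc, p_value = p, bin_level = NA_real_,
      reason = NA_character_, stringsAsFactors = FALSE))
  }
  # uncorrectable: test against the predicted null of the taller profile's
  # half-decade intensity bin
  apex <- max(profile_apex(p1$y1, p1$interval),
              profile_apex(p2$y1, p2$interval))
  bin <- round(log10(apex) * 2) / 2
  key <- sprintf("%.1f", bin)
  if (!exists(key, envir = null_cache, inherits = FALSE)) {
    assign(key,
           predict_null(exp_null, library, template = config$template,
                        level = 10^bin, n_draws = config$n_draws,
                        seed = config$seed + round(bin * 2)),
           envir = null_cache)
  }
  pred <- get(key, envir = null_cache, inherits = FALSE)
  fc <- a2_before / a1_before
  data.frame(
    sequence = p1$peptide$sequence, charge = p1$peptide$charge,
    abundance_before_1 = a1_before, abundance_before_2 = a2_before,
    correctable = FALSE,
    abundance_after_1 = a1_before, abundance_after_2 = a2_before,
    fold_change = fc, p_value = fold_change_pvalue(fc, pred),
    bin_level = 10^bin, reason = NA_character_, stringsAsFactors = FALSE)
}

#' Export a null distribution to TSV
#'
#' One column `log10_ratio`.
#'
#' @param null A `null_distribution`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_null <- function(null, path) {
  stopifnot(inherits(null, "null_distribution"))
  utils::write.table(data.frame(log10_ratio = null$log_ratios), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a null distribution from TSV
#'
#' @param path TSV with a `log10_ratio` column.
#' @param kind Kind tag for the loaded distribution.
#' @return A `null_distribution`.
#' @export
read_null <- function(path, kind = "experimental") {
  df <- utils::read.delim(path, sep = "\t")
  if (!"log10_ratio" %in% names(df)) stop("null file lacks column log10_ratio")
  null_distribution(df$log10_ratio, kind = kind)
}
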