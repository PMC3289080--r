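# Ground-truthed synthetic LC-FTMS data: isotope-pair profiles, whole 1:1
# run pairs, and minimal mzXML fixtures. The generator realises the
# suppression model the package estimates: Gaussian elution peaks, one true
# isotope ratio per peptide, an intensity-dependent monotone distortion that
# is identical for both isotopes of a peptide (and for both runs) but varies
# across peptides, multiplicative measurement noise, and lognormal
# between-run variation centred at ratio 1.

#' Construct a distortion specification
#'
#' The power-law family is the generator's model of intensity-dependent
#' suppression: in log10 space the distortion is linear below the
#' distortion-free threshold with slope `gamma > 1`,
#' `g(x) = threshold * (x/threshold)^gamma` for `x < threshold`, the identity
#' above it. Larger gamma means more severe suppression at low intensity;
#' the map is continuous at the threshold.
#'
#' @param family `"identity"` or `"power_law"`.
#' @param gamma Power-law exponent, > 1 (ignored for identity).
#' @param threshold Distortion-free lower limit in ion counts (default 1e6).
#' @return A list of class `distortion_spec` with callable elements
#'   `g` (true -> observed) and `f` (observed -> true), exact inverses.
#' @examples
#' d <- make_distortion("power_law", gamma = 2)
#' d$g(1e4)   # 1e2
#' d$f(d$g(12345))
#' @export
make_distortion <- function(family = c("identity", "power_law"), gamma = NULL,
                            threshold = 1e6) {
  family <- match.arg(family)
  stopifnot(threshold > 0)
  if (family == "identity") {
    g <- identity
    f <- identity
    gamma <- 1
  } else {
    if (is.null(gamma) || gamma <= 1) {
      stop("power_law distortion requires gamma > 1")
    }
    force(threshold)
    g <- function(x) ifelse(x > 0 & x < threshold,
                            threshold * (x / threshold)^gamma, x)
    f <- function(y) ifelse(y > 0 & y < threshold,
                            threshold * (y / threshold)^(1 / gamma), y)
  }
  structure(list(family = family, gamma = gamma, threshold = threshold,
                 g = g, f = f),
            class = "distortion_spec")
}

# Gaussian elution shape on a scan grid (1 s per scan), apex 1 at `center`.
.gauss_shape <- function(n_scans, center, sd_scans) {
  i <- seq_len(n_scans)
  exp(-0.5 * ((i - center) / sd_scans)^2)
}

# lognormal multiplicative noise with unit mean and given CV
.mult_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate one synthetic isotope pair with known truth
#'
#' The true monoisotopic profile x1 is Gaussian with the stated apex; the
#' true heavy-isotope profile is `x2 = r * x1` pointwise. Both observed
#' profiles pass through the same distortion `g` and receive independent
#' multiplicative lognormal noise.
#'
#' @param true_apex Apex of the true monoisotopic profile, ion counts.
#' @param r True isotope ratio in (0, 1).
#' @param distortion A [make_distortion()] spec.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0, noise-free).
#' @param n_scans Number of scans (1 s spacing, default 61).
#' @param shape_sd Gaussian elution SD in scans (default 5).
#' @param seed Optional integer seed; fixes the noise draw.
#' @return A list with `pair` (an `isotope_pair` with detected peak
#'   interval) and `truth` (true profiles `x1`, `x2`, the distortion, and
#'   true areas over the pair's interval).
#' @export
generate_pair <- function(true_apex, r, distortion = make_distortion(),
                          noise_cv = 0, n_scans = 61, shape_sd = 5,
                          seed = NULL) {
  stopifnot(true_apex > 0, r > 0, r < 1,
            inherits(distortion, "distortion_spec"), n_scans >= 7)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  times <- seq(0, by = 1, length.out = n_scans)
  center <- (n_scans + 1) / 2
  x1 <- true_apex * .gauss_shape(n_scans, center, shape_sd)
  x2 <- r * x1
  y1 <- distortion$g(x1) * .mult_noise(n_scans, noise_cv)
  y2 <- distortion$g(x2) * .mult_noise(n_scans, noise_cv)
  p1 <- elution_profile(times, y1)
  interval <- detect_peak_interval(p1, rt_hint = times[round(center)],
                                   rt_window = n_scans)
  pep <- list(sequence = "SYNTHETIC", charge = 2L,
              elution_time = times[round(center)], id_probability = 1)
  pair <- isotope_pair(p1, elution_profile(times, y2), r, peptide = pep,
                       interval = interval)
  tx1 <- elution_profile(times, x1)
  tx2 <- elution_profile(times, x2)
  list(pair = pair,
       truth = list(x1 = tx1, x2 = tx2, distortion = distortion,
                    area1 = profile_area(tx1, interval),
                    area2 = profile_area(tx2, interval)))
}

#' Specification of a synthetic 1:1 run pair
#'
#' Defaults describe a label-free replicate pair on one sample: 200
#' peptides with true apexes log-uniform over 1e4-1e7 ion counts, isotope
#' ratios uniform on 0.2-0.8, one power-law distortion per peptide with
#' exponent uniform on 1.1-2.0 shared by both isotopes and both runs, 1%
#' multiplicative measurement noise, and between-run lognormal variation of
#' 0.05 in log10 per run.
#'
#' @param n_peptides Number of peptides (default 200).
#' @param apex_range Log-uniform bounds of the true apex (default
#'   `c(1e4, 1e7)`).
#' @param r_range Isotope-ratio bounds (default `c(0.2, 0.8)`). Ignored when
#'   `use_theoretical_r = TRUE`.
#' @param gamma_range Power-law exponent bounds (default `c(1.1, 2)`); a
#'   gamma of exactly 1 means no distortion.
#' @param sigma_log10 SD of each run's lognormal abundance factor on the
#'   log10 scale (default 0.05); both runs vary independently, so
#'   suppression-free log10 fold changes have SD `sigma_log10 * sqrt(2)`.
#' @param noise_cv Multiplicative measurement-noise CV (default 0.01).
#' @param n_scans Scans per run at 1 s spacing (default 200).
#' @param shape_sd Gaussian elution SD in scans (default 5).
#' @param threshold Distortion-free lower limit (default 1e6).
#' @param use_theoretical_r If TRUE, each peptide's isotope ratio is computed
#'   from its (randomly drawn) sequence rather than drawn from `r_range`;
#'   required for fixtures that will be re-read through the mzXML pipeline,
#'   where the ratio is recomputed from the sequence.
#' @param seed Integer seed fixing every draw (default 1).
#' @return A list of class `run_spec`.
#' @export
run_spec <- function(n_peptides = 200, apex_range = c(1e4, 1e7),
                     r_range = c(0.2, 0.8), gamma_range = c(1.1, 2),
                     sigma_log10 = 0.05, noise_cv = 0.01, n_scans = 200,
                     shape_sd = 5, threshold = 1e6,
                     use_theoretical_r = FALSE, seed = 1) {
  stopifnot(n_peptides >= 1, apex_range[1] > 0, diff(apex_range) > 0,
            r_range[1] > 0, r_range[2] < 1, diff(r_range) >= 0,
            gamma_range[1] >= 1, diff(gamma_range) >= 0,
            sigma_log10 >= 0, noise_cv >= 0, n_scans >= 30, threshold > 0)
  structure(as.list(environment()), class = "run_spec")
}

#' Generate a synthetic 1:1 label-free run pair with truth table
#'
#' Two runs share true peptide abundances up to independent lognormal
#' between-run factors; each peptide keeps its own distortion in both runs.
#' Elution centres are spread over the run, so each profile sits on the full
#' run time grid.
#'
#' @param spec A [run_spec()].
#' @return A list with `run1`, `run2` (lists of `isotope_pair`, matched by
#'   position and by peptide sequence/charge) and `truth` (data frame with
#'   sequence, charge, mz1, mz2, r, gamma, true apexes and true areas per
#'   run).
#' @export
generate_run_pair <- function(spec = run_spec()) {
  stopifnot(inherits(spec, "run_spec"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  n <- spec$n_peptides
  seqs <- .draw_sequences(n, min_mz_gap = 0.05)
  charge <- rep(2L, n)
  comps <- lapply(seqs, elemental_composition)
  mz1 <- vapply(seq_len(n), function(i) monoisotopic_mz(comps[[i]], charge[i]),
                numeric(1))
  mz2 <- vapply(seq_len(n), function(i) isotope13_mz(mz1[i], charge[i]),
                numeric(1))
  r <- if (spec$use_theoretical_r) {
    vapply(comps, theoretical_isotope_ratio, numeric(1))
  } else {
    stats::runif(n, spec$r_range[1], spec$r_range[2])
  }
  gamma <- stats::runif(n, spec$gamma_range[1], spec$gamma_range[2])
  base_apex <- 10^stats::runif(n, log10(spec$apex_range[1]),
                               log10(spec$apex_range[2]))
  fac1 <- 10^stats::rnorm(n, 0, spec$sigma_log10)
  fac2 <- 10^stats::rnorm(n, 0, spec$sigma_log10)
  margin <- ceiling(4 * spec$shape_sd)
  centers <- stats::runif(n, margin, spec$n_scans - margin)
  times <- seq(0, by = 1, length.out = spec$n_scans)

  build_run <- function(apexes) {
    lapply(seq_len(n), function(i) {
      d <- if (gamma[i] > 1) {
        make_distortion("power_law", gamma = gamma[i],
                        threshold = spec$threshold)
      } else make_distortion("identity", threshold = spec$threshold)
      x1 <- apexes[i] * .gauss_shape(spec$n_scans, centers[i], spec$shape_sd)
      x2 <- r[i] * x1
      y1 <- d$g(x1) * .mult_noise(spec$n_scans, spec$noise_cv)
      y2 <- d$g(x2) * .mult_noise(spec$n_scans, spec$noise_cv)
      p1 <- elution_profile(times, y1)
      interval <- tryCatch(
        detect_peak_interval(p1, rt_hint = centers[i], rt_window = 120),
        error = function(e) NULL)
      pep <- list(sequence = seqs[i], charge = charge[i],
                  elution_time = centers[i], id_probability = 0.99,
                  mz1 = mz1[i], mz2 = mz2[i])
      isotope_pair(p1, elution_profile(times, y2), r[i], peptide = pep,
                   interval = interval)
    })
  }
  run1 <- build_run(base_apex * fac1)
  run2 <- build_run(base_apex * fac2)
  shape_area <- sum(.gauss_shape(spec$n_scans, spec$n_scans / 2,
                                 spec$shape_sd))  # 1 s spacing
  truth <- data.frame(
    sequence = seqs, charge = charge, mz1 = mz1, mz2 = mz2, r = r,
    gamma = gamma,
    apex1 = base_apex * fac1, apex2 = base_apex * fac2,
    true_area1 = base_apex * fac1 * shape_area,
    true_area2 = base_apex * fac2 * shape_area,
    stringsAsFactors = FALSE)
  list(run1 = run1, run2 = run2, truth = truth, spec = spec)
}

# Random tryptic-looking sequences whose charge-2 m/z are pairwise separated
# (so XIC windows cannot cross-contaminate); deterministic under the caller's
# RNG state.
.draw_sequences <- function(n, min_mz_gap = 0.05, max_tries = 60L) {
  residues <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]  # no K/R internal
  seqs <- character(0)
  mzs <- numeric(0)
  tries <- 0L
  while (length(seqs) < n) {
    tries <- tries + 1L
    if (tries > max_tries * n) stop("could not draw non-overlapping m/z set")
    len <- sample(8:14, 1L)
    s <- paste(c(sample(residues, len - 1L, replace = TRUE),
                 sample(c("K", "R"), 1L)), collapse = "")
    comp <- elemental_composition(s)
    mz <- monoisotopic_mz(comp, 2L)
    if (s %in% seqs) next
    # keep the pairing usable: theoretical M+1/M ratio away from 0 and 1
    rr <- theoretical_isotope_ratio(comp)
    if (rr < 0.1 || rr > 0.9) next
    if (length(mzs) && min(abs(mzs - mz)) < min_mz_gap) next
    # keep the M+1 window clear of other peptides' monoisotopic peaks too
    if (length(mzs) && min(abs(mzs - (mz + .c13_shift / 2))) < min_mz_gap) next
    if (length(mzs) && min(abs((mzs + .c13_shift / 2) - mz)) < min_mz_gap) next
    seqs <- c(seqs, s)
    mzs <- c(mzs, mz)
  }
  seqs
}

#' Write a synthetic run to a minimal mzXML fixture
#'
#' Each peptide contributes two peaks per scan (monoisotopic and M+1 m/z,
#' computed from its sequence and charge). Peaks are base64-encoded in
#' network byte order; the file is readable by [read_mzxml()]. A matching
#' peptide-list TSV can be written alongside.
#'
#' @param run List of `isotope_pair` as produced by [generate_run_pair()]
#'   (peptides must carry `mz1`/`mz2`).
#' @param path Output mzXML path.
#' @param peptide_list_path Optional path for the companion TSV peptide list.
#' @param precision Peak encoding, 32 or 64 bit floats (default 32).
#' @param compression `"none"` or `"zlib"`.
#' @return `path`, invisibly.
#' @export
write_mzxml_fixture <- function(run, path, peptide_list_path = NULL,
                                precision = 32, compression = c("none", "zlib")) {
  compression <- match.arg(compression)
  stopifnot(precision %in% c(32, 64))
  if (length(run) == 0L) stop("empty run: nothing to write")
  stopifnot(all(vapply(run, inherits, logical(1), "isotope_pair")))
  times <- run[[1]]$y1$times
  for (p in run) stopifnot(isTRUE(all.equal(p$y1$times, times)))
  mz1 <- vapply(run, function(p) p$peptide$mz1, numeric(1))
  mz2 <- vapply(run, function(p) p$peptide$mz2, numeric(1))
  size <- precision / 8
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="ISO-8859-1"?>',
    '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">',
    sprintf(' <msRun scanCount="%d">', length(times))), con)
  for (s in seq_along(times)) {
    i1 <- vapply(run, function(p) p$y1$intensities[s], numeric(1))
    i2 <- vapply(run, function(p) p$y2$intensities[s], numeric(1))
    mz <- c(mz1, mz2); int <- c(i1, i2)
    keep <- int > 0
    mz <- mz[keep]; int <- int[keep]
    o <- order(mz); mz <- mz[o]; int <- int[o]
    raw <- writeBin(as.numeric(rbind(mz, int)), raw(), size = size,
                    endian = "big")
    comp_attr <- ' compressionType="none" compressedLen="0"'
    if (compression == "zlib") {
      raw <- memCompress(raw, "gzip")
      comp_attr <- sprintf(' compressionType="zlib" compressedLen="%d"',
                           length(raw))
    }
    writeLines(sprintf(
      paste0('  <scan num="%d" msLevel="1" peaksCount="%d"',
             ' retentionTime="PT%.4fS">\n',
             '   <peaks precision="%d" byteOrder="network"',
             ' contentType="m/z-int"%s>%s</peaks>\n  </scan>'),
      s, length(mz), times[s], precision, comp_attr,
      gsub("[\r\n]", "", jsonlite::base64_enc(raw))), con)
  }
  writeLines(c(' </msRun>', ' <index name="scan"></index>',
               ' <indexOffset>0</indexOffset>', '</mzXML>'), con)
  if (!is.null(peptide_list_path)) {
    df <- data.frame(
      sequence = vapply(run, function(p) p$peptide$sequence, character(1)),
      charge = vapply(run, function(p) p$peptide$charge, integer(1)),
      elution_time = vapply(run, function(p) p$peptide$elution_time,
                            numeric(1)),
      probability = vapply(run, function(p) p$peptide$id_probability,
                           numeric(1)))
    utils::write.table(df, peptide_list_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
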