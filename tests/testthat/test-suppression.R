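suppressive_pairs <- function(n, gamma = seq(1.2, 2, length.out = n),
                              r = 0.4, apex = 6e6, noise = 0) {
  lapply(seq_len(n), function(i) {
    p <- generate_pair(apex, r, make_distortion("power_law", gamma[i]),
                       noise_cv = noise, seed = 100 + i)$pair
    p$peptide$sequence <- sprintf("SYN%03d", i)
    p
  })
}

test_that("the library keeps correctable fits and logs skip reasons", {
  pairs <- suppressive_pairs(5)
  lib <- build_function_library(pairs)
  expect_s3_class(lib, "function_library")
  expect_length(lib, 5L)
  low <- lapply(1:2, function(i)
    generate_pair(3e5, 0.4, make_distortion("power_law", 1.5),
                  seed = i)$pair)
  lib2 <- build_function_library(c(pairs[1:3], low))
  expect_length(lib2, 3L)
  expect_equal(nrow(lib2$skipped), 2L)
  expect_true(all(lib2$skipped$reason == "below_intensity_limit"))
  expect_error(build_function_library(low), "below_intensity_limit")
})

test_that("pairs sharing one distortion yield agreeing library members", {
  d <- make_distortion("power_law", 1.5)
  pairs <- lapply(c(0.3, 0.5, 0.7), function(r)
    generate_pair(2.5e6 / r, r, d)$pair)
  lib <- build_function_library(pairs)
  lo <- max(vapply(lib$functions, function(f) f$valid_range[1], numeric(1)))
  yy <- 10^seq(log10(lo), 6, length.out = 20)
  vals <- sapply(lib$functions, function(f) correct_intensity(f, yy))
  spread <- apply(vals, 1, function(v) diff(range(v)) / min(v))
  expect_lt(max(spread), 0.05)
})

test_that("suppression statistics match direct evaluation of the distortion", {
  idlib <- function_library(list(identity_correction(),
                                 identity_correction()))
  st <- suppression_statistics(idlib, levels = c(1e4, 1e5, 1e6))
  expect_equal(st$mean, rep(1, 3))
  expect_equal(st$sd, rep(0, 3))
  # single power-law member: compare to numeric integration with the
  # generator's closed-form g
  gamma <- 1.5
  k <- 10^seq(1, 6, by = 0.5)
  f <- correction_function(k, 1e6 * (k / 1e6)^(1 / gamma))
  lib1 <- function_library(list(f))
  tpl <- default_template()
  st1 <- suppression_statistics(lib1, tpl, levels = 1e5)
  d <- make_distortion("power_law", gamma)
  scaled <- tpl$intensities * 1e5
  expected <- oracle_trapz(tpl$times, d$g(scaled)) /
    oracle_trapz(tpl$times, scaled)
  expect_equal(st1$mean, expected, tolerance = 1e-6)
  expect_lt(st1$mean, 1)
  # heterogeneous library: spread grows as the level drops
  lib <- build_function_library(suppressive_pairs(6))
  st <- suppression_statistics(lib, levels = c(1e4, 1e5, 5e6))
  expect_true(all(diff(st$sd) <= 0))
  expect_gt(st$sd[1], 0)
})

test_that("experimental null reflects pure between-run scaling", {
  pairs <- suppressive_pairs(6, gamma = rep(1.3, 6), apex = 5e6)
  en <- suppressWarnings(experimental_null(pairs, pairs))
  expect_equal(en$log_ratios, rep(0, 6))
  scaled <- lapply(pairs, function(p) {
    isotope_pair(elution_profile(p$y1$times, 1.1 * p$y1$intensities),
                 elution_profile(p$y2$times, 1.1 * p$y2$intensities),
                 p$r, p$peptide, p$interval)
  })
  en2 <- suppressWarnings(experimental_null(pairs, scaled))
  expect_equal(en2$log_ratios, rep(log10(1.1), 6), tolerance = 1e-12)
  expect_warning(experimental_null(pairs, pairs), "< 30")
  expect_error(experimental_null(pairs[1:3], pairs[1:3]), "at least 5")
})

test_that("experimental null recovers the generator's scatter", {
  set.seed(21)
  base <- suppressive_pairs(100, gamma = rep(1.2, 100), apex = 4e6)
  fac <- 10^rnorm(100, 0, 0.05)
  run2 <- lapply(seq_along(base), function(i) {
    p <- base[[i]]
    pep <- p$peptide; pep$sequence <- sprintf("PEP%03d", i)
    isotope_pair(elution_profile(p$y1$times, fac[i] * p$y1$intensities),
                 elution_profile(p$y2$times, fac[i] * p$y2$intensities),
                 p$r, pep, p$interval)
  })
  run1 <- lapply(seq_along(base), function(i) {
    p <- base[[i]]; p$peptide$sequence <- sprintf("PEP%03d", i); p
  })
  en <- experimental_null(run1, run2)
  expect_length(en$log_ratios, 100L)
  expect_equal(sd(en$log_ratios), 0.05, tolerance = 0.2)
})

test_that("an identity library transports the experimental null unchanged", {
  set.seed(6)
  en <- null_distribution(rnorm(100, 0, 0.07), kind = "experimental")
  idlib <- function_library(list(identity_correction()))
  pn <- predict_null(en, idlib, level = 1e5, n_draws = 2000, seed = 3)
  nearest <- vapply(pn$log_ratios,
                    function(v) min(abs(v - en$log_ratios)), numeric(1))
  expect_lt(max(nearest), 1e-9)
  expect_gt(ks_compare(pn, en)$p_value, 0.05)
  # concentrated null: every draw is ratio 1, suppression cancels exactly
  en1 <- null_distribution(rep(0, 50), kind = "experimental")
  lib <- build_function_library(suppressive_pairs(3))
  pn1 <- predict_null(en1, lib, level = 1e5, n_draws = 20, seed = 1)
  expect_equal(pn1$log_ratios, rep(0, length(pn1$log_ratios)),
               tolerance = 1e-12)
})

test_that("predicted nulls widen as the intensity level drops", {
  en <- null_distribution(rnorm(80, 0, 0.07), kind = "experimental")
  lib <- build_function_library(suppressive_pairs(5))
  sd_low <- sd(predict_null(en, lib, level = 1e5, n_draws = 400,
                            seed = 2)$log_ratios)
  sd_high <- sd(predict_null(en, lib, level = 5e6, n_draws = 400,
                             seed = 2)$log_ratios)
  expect_gt(sd_low, sd_high)
  # same seed and inputs give bit-identical draws
  a <- predict_null(en, lib, level = 1e5, n_draws = 100, seed = 7)
  b <- predict_null(en, lib, level = 1e5, n_draws = 100, seed = 7)
  expect_identical(a$log_ratios, b$log_ratios)
})

test_that("KS comparison behaves at the extremes", {
  x <- rnorm(50)
  same <- ks_compare(x, x)
  expect_equal(same$D, 0)
  expect_equal(same$p_value, 1)
  set.seed(13)
  far <- ks_compare(rnorm(200), rnorm(200, 5))
  expect_lt(far$p_value, 1e-6)
})

test_that("empirical P-values are valid, centered and monotone", {
  set.seed(17)
  lr <- rnorm(99, 0, 0.1)
  null <- null_distribution(lr, kind = "experimental")
  expect_equal(fold_change_pvalue(10^median(lr), null), 1)
  extreme <- 10^(median(lr) + max(abs(lr - median(lr))) + 1)
  expect_equal(fold_change_pvalue(extreme, null), 1 / 100)
  fcs <- 10^seq(median(lr), median(lr) + 0.5, length.out = 20)
  ps <- vapply(fcs, fold_change_pvalue, numeric(1), null = null)
  expect_true(all(ps > 0 & ps <= 1))
  expect_true(all(diff(ps) <= 0))
})

test_that("P-values of null-drawn fold changes are near uniform", {
  set.seed(23)
  null <- null_distribution(rnorm(1000, 0, 0.07), kind = "experimental")
  ps <- vapply(10^rnorm(200, 0, 0.07), fold_change_pvalue, numeric(1),
               null = null)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("significance assignment handles a 1:1 pair end to end", {
  rp <- generate_run_pair(run_spec(n_peptides = 60, apex_range = c(5e5, 1e7),
                                   seed = 31))
  lib <- build_function_library(c(rp$run1, rp$run2))
  en <- experimental_null(rp$run1, rp$run2)
  res <- assign_significance(rp$run1, rp$run2, lib, en,
                             analysis_config(n_draws = 300, seed = 4))
  expect_equal(nrow(res), 60L)
  ok <- !is.na(res$p_value)
  expect_gt(mean(ok), 0.9)
  expect_true(all(res$p_value[ok] > 0 & res$p_value[ok] <= 1))
  expect_true(any(res$correctable))
  # uncorrectable peptides keep their observed abundances
  un <- !res$correctable & ok
  expect_equal(res$abundance_after_1[un], res$abundance_before_1[un])
  expect_equal(res$abundance_after_2[un], res$abundance_before_2[un])
})

test_that("suppression widens the null an uncorrectable peptide is tested on", {
  set.seed(41)
  en <- null_distribution(rnorm(200, 0, 0.05), kind = "experimental")
  lib <- build_function_library(suppressive_pairs(5))
  pred <- predict_null(en, lib, level = 1e5, n_draws = 500, seed = 9)
  expect_gt(sd(pred$log_ratios), sd(en$log_ratios))
  fc <- 10^0.12
  expect_gt(fold_change_pvalue(fc, pred), fold_change_pvalue(fc, en))
})

test_that("null distributions round-trip through TSV", {
  nd <- null_distribution(rnorm(40, 0, 0.1), kind = "experimental")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_null(nd, path)
  back <- read_null(path)
  expect_equal(back$log_ratios, nd$log_ratios, tolerance = 1e-12)
})
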