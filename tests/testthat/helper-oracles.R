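# Independent oracles used across tests; deliberately written without
# reference to the package's own algorithms.

# Natural abundances by nominal mass shift (same physical constants the
# package uses; the *algorithm* below is independent).
.ab <- list(C = c(0.9893, 0.0107),
            H = c(0.999885, 0.000115),
            N = c(0.99636, 0.00364),
            O = c(0.99757, 0.00038, 0.00205),
            S = c(0.9499, 0.0075, 0.0425, 0, 0.0001))

# Brute-force isotopologue enumeration: probability of the all-light
# molecule and of every single-heavy(+1) substitution, as explicit products.
oracle_m1_ratio <- function(comp) {
  comp <- comp[comp > 0]
  p_mono <- prod(vapply(names(comp), function(e) .ab[[e]][1]^comp[[e]],
                        numeric(1)))
  p_m1 <- 0
  for (e in names(comp)) {
    a <- .ab[[e]]
    if (length(a) < 2 || a[2] == 0) next
    # choose which one of the n identical atoms is heavy: n ways
    rest <- prod(vapply(setdiff(names(comp), e),
                        function(e2) .ab[[e2]][1]^comp[[e2]], numeric(1)))
    p_m1 <- p_m1 + comp[[e]] * a[1]^(comp[[e]] - 1) * a[2] * rest
  }
  p_m1 / p_mono
}

# hand trapezoid
oracle_trapz <- function(t, y) sum(diff(t) * (y[-length(y)] + y[-1]) / 2)

# zero-padded 3-point moving average (the smoother peak detection uses)
.movavg3_oracle <- function(y) {
  n <- length(y); pad <- c(0, y, 0)
  (pad[1:n] + pad[2:(n + 1)] + pad[3:(n + 2)]) / 3
}

random_sequences <- function(n, min_len = 5, max_len = 30) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(aa, sample(min_len:max_len, 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

# scan_collection built in code from explicit peaks
toy_scans <- function(times, peak_list) {
  scan_collection(times,
                  lapply(peak_list, function(p) p$mz),
                  lapply(peak_list, function(p) p$int))
}
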