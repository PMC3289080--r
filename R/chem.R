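# Peptide chemistry: elemental composition, monoisotopic m/z, and the
# theoretical M+1 / M isotope intensity ratio that anchors the correction.

# Residue (amino acid minus water) elemental compositions, C/H/N/O/S.
.residue_comp <- matrix(c(
  # C   H  N  O  S
    3,  5, 1, 1, 0,  # A
    6, 12, 4, 1, 0,  # R
    4,  6, 2, 2, 0,  # N
    4,  5, 1, 3, 0,  # D
    3,  5, 1, 1, 1,  # C
    5,  7, 1, 3, 0,  # E
    5,  8, 2, 2, 0,  # Q
    2,  3, 1, 1, 0,  # G
    6,  7, 3, 1, 0,  # H
    6, 11, 1, 1, 0,  # I
    6, 11, 1, 1, 0,  # L
    6, 12, 2, 1, 0,  # K
    5,  9, 1, 1, 1,  # M
    9,  9, 1, 1, 0,  # F
    5,  7, 1, 1, 0,  # P
    3,  5, 1, 2, 0,  # S
    4,  7, 1, 2, 0,  # T
   11, 10, 2, 1, 0,  # W
    9,  9, 1, 2, 0,  # Y
    5,  9, 1, 1, 0   # V
), ncol = 5, byrow = TRUE,
  dimnames = list(strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]],
                  c("C", "H", "N", "O", "S")))

# Monoisotopic masses (IUPAC/CODATA), Da.
.mono_mass <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                O = 15.9949146221, S = 31.97207069)
.proton_mass <- 1.00727646688
.c13_shift <- 1.0033548378  # 13C - 12C mass difference

# Natural isotope abundances by nominal mass shift from the lightest isotope.
.isotope_abundance <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
)

#' Elemental composition of a peptide
#'
#' Sums the standard residue compositions of an unmodified peptide and adds
#' one water for the termini. Only the 20 standard residues are accepted.
#'
#' @param sequence Uppercase amino-acid string.
#' @return Named integer vector with counts of C, H, N, O, S for the neutral
#'   peptide.
#' @examples
#' elemental_composition("PEPTIDE")
#' @export
elemental_composition <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("sequence must be a non-empty amino-acid string")
  }
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, rownames(.residue_comp))
  if (length(bad)) {
    stop(sprintf("unknown residue '%s' in sequence '%s'", bad[1], sequence))
  }
  comp <- colSums(.residue_comp[aa, , drop = FALSE])
  comp[["H"]] <- comp[["H"]] + 2L  # + H2O
  comp[["O"]] <- comp[["O"]] + 1L
  storage.mode(comp) <- "integer"
  comp
}

#' Monoisotopic m/z of a peptide ion
#'
#' @param composition Named counts of C, H, N, O, S (see
#'   [elemental_composition()]).
#' @param charge Positive integer charge state; protonation is assumed.
#' @return m/z in Thomson.
#' @examples
#' monoisotopic_mz(elemental_composition("PEPTIDE"), charge = 2)
#' @export
monoisotopic_mz <- function(composition, charge) {
  stopifnot(charge >= 1, charge == as.integer(charge))
  composition <- .check_composition(composition)
  m <- sum(composition * .mono_mass[names(composition)])
  (m + charge * .proton_mass) / charge
}

#' m/z of the first heavy-isotope (13C) species
#'
#' @param mono_mz Monoisotopic m/z in Thomson.
#' @param charge Positive integer charge state.
#' @return m/z of the M+1 species: `mono_mz + 1.0033548/charge`.
#' @export
isotope13_mz <- function(mono_mz, charge) {
  stopifnot(charge >= 1)
  mono_mz + .c13_shift / charge
}

#' Theoretical M+1 / monoisotopic intensity ratio
#'
#' The intensity ratio between the first heavy isotope peak (one nominal mass
#' unit above monoisotopic, dominated by single 13C substitution) and the
#' monoisotopic peak, from exact convolution of the per-element natural
#' isotope distributions over nominal mass shift.
#'
#' @param composition Named counts of C, H, N, O, S.
#' @return The ratio r, positive; for the isotope-pair constraint used in
#'   suppression correction only values in (0, 1) are usable.
#' @examples
#' theoretical_isotope_ratio(elemental_composition("PEPTIDE"))
#' @export
theoretical_isotope_ratio <- function(composition) {
  composition <- .check_composition(composition)
  if (sum(composition) == 0L) stop("empty composition")
  # Convolve per-element shift polynomials; only shifts 0..3 are retained,
  # which leaves the 0 and +1 coefficients exact.
  dist <- 1
  for (e in names(composition)) {
    n <- composition[[e]]
    if (n > 0) dist <- .conv_trunc(dist, .poly_pow(.isotope_abundance[[e]], n))
  }
  dist[2] / dist[1]
}

.check_composition <- function(composition) {
  if (is.null(names(composition)) ||
      !all(names(composition) %in% c("C", "H", "N", "O", "S"))) {
    stop("composition must be named counts of C, H, N, O, S")
  }
  if (any(composition < 0)) stop("negative element count")
  composition[composition > 0]
}

.MAX_SHIFT <- 4L  # polynomial truncation length (shifts 0..3)

.conv_trunc <- function(a, b) {
  n <- min(.MAX_SHIFT, length(a) + length(b) - 1L)
  out <- numeric(n)
  for (i in seq_along(a)) {
    j <- seq_len(min(length(b), n - i + 1L))
    out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
  }
  out
}

.poly_pow <- function(p, n) {
  # exponentiation by squaring with truncation at .MAX_SHIFT terms
  out <- 1
  base <- p
  while (n > 0) {
    if (n %% 2 == 1) out <- .conv_trunc(out, base)
    base <- .conv_trunc(base, base)
    n <- n %/% 2
  }
  out
}
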