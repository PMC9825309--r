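# Peptide chemistry: elemental compositions, monoisotopic masses, fragment m/z
# and aggregated isotope envelopes.

PROTON_MASS <- 1.007276466
# aggregate spacing between adjacent isotope peaks (averagine-style), Da
NEUTRON_MASS_DELTA <- 1.00286864

# residue (water-free) elemental compositions for the 20 standard amino acids
RESIDUE_COMPOSITIONS <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6, N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

WATER_COMPOSITION <- c(C = 0, H = 2, N = 0, O = 1, S = 0)
# carbamidomethyl delta (iodoacetamide alkylation of Cys): +C2H3NO
CARBAMIDOMETHYL_COMPOSITION <- c(C = 2, H = 3, N = 1, O = 1, S = 0)

.chem_env <- new.env(parent = emptyenv())

#' Bundled isotope table
#'
#' Monoisotopic masses and natural abundances for the elements handled by the
#' simulator (C, H, N, O, P, S), from standard IUPAC values, shipped as a
#' plain-text file under `inst/extdata/isotopes.tsv`.
#'
#' @return A tibble with columns `element`, `nucleons`, `mass`, `abundance`.
#' @export
#' @examples
#' isotope_table()
isotope_table <- function() {
  if (is.null(.chem_env$isotopes)) {
    path <- system.file("extdata", "isotopes.tsv", package = "diasimr",
                        mustWork = TRUE)
    .chem_env$isotopes <- readr::read_tsv(path, show_col_types = FALSE)
  }
  .chem_env$isotopes
}

# cached element -> lightest-isotope mass lookup
.monoisotopic_masses <- function() {
  if (is.null(.chem_env$mono_masses)) {
    iso <- isotope_table()
    mono <- iso |>
      dplyr::group_by(.data$element) |>
      dplyr::summarise(mass = .data$mass[which.min(.data$nucleons)])
    .chem_env$mono_masses <- setNames(mono$mass, mono$element)
  }
  .chem_env$mono_masses
}

#' Elemental composition of a peptide
#'
#' Sums the water-free residue compositions of the sequence, adds one water
#' for the intact peptide and, when `carbamidomethyl = TRUE`, one C2H3NO per
#' cysteine. Carbamidomethyl-Cys is the only modification the simulator
#' supports; all other residues are taken unmodified.
#'
#' @param sequence Amino-acid string using the 20 standard one-letter codes.
#' @param carbamidomethyl Apply the fixed carbamidomethyl modification to every
#'   cysteine (default `TRUE`, the conventional fixed modification).
#' @return Named integer vector of element counts (C, H, N, O, S).
#' @export
#' @examples
#' peptide_composition("PEPTIDE")
peptide_composition <- function(sequence, carbamidomethyl = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  residues <- strsplit(sequence, "", fixed = TRUE)[[1]]
  unknown <- which(!residues %in% names(RESIDUE_COMPOSITIONS))
  if (length(unknown)) {
    abort(sprintf("unknown residue '%s' at position %d in sequence '%s'",
                  residues[unknown[1]], unknown[1], sequence))
  }
  comp <- Reduce(`+`, RESIDUE_COMPOSITIONS[residues]) + WATER_COMPOSITION
  if (isTRUE(carbamidomethyl)) {
    comp <- comp + CARBAMIDOMETHYL_COMPOSITION * sum(residues == "C")
  }
  comp
}

#' Monoisotopic mass of an elemental composition
#'
#' @param composition Named numeric vector of non-negative element counts;
#'   names must exist in [isotope_table()].
#' @return Mass in Da: sum of count times the lightest-isotope exact mass.
#' @export
#' @examples
#' monoisotopic_mass(c(H = 2, O = 1)) # water
monoisotopic_mass <- function(composition) {
  composition <- composition[composition != 0]
  if (!length(composition)) return(0)
  masses <- .monoisotopic_masses()
  missing <- setdiff(names(composition), names(masses))
  if (length(missing)) {
    abort(paste0("element(s) not in the bundled isotope table: ",
                 paste(missing, collapse = ", ")))
  }
  sum(composition * masses[names(composition)])
}

#' m/z of an ion from its neutral mass and charge
#'
#' @param neutral_mass Neutral monoisotopic mass, Da.
#' @param charge Positive integer charge (protonation assumed).
#' @return m/z in Th: `(neutral_mass + charge * proton) / charge`.
#' @export
ion_mz <- function(neutral_mass, charge) {
  if (any(charge < 1)) abort("charge must be >= 1")
  (neutral_mass + charge * PROTON_MASS) / charge
}

#' b/y fragment ion m/z
#'
#' Computes singly or multiply protonated b- and y-series fragment m/z for HCD
#' style backbone cleavage: b ions are the N-terminal residue sum, y ions the
#' C-terminal residue sum plus water.
#'
#' @inheritParams peptide_composition
#' @param series `"b"` or `"y"`.
#' @param index Fragment index, `1 <= index <= nchar(sequence) - 1`.
#' @param charge Fragment charge (default 1).
#' @return Fragment m/z in Th.
#' @export
#' @examples
#' fragment_mz("PEPTIDEK", "y", 3)
fragment_mz <- function(sequence, series = c("b", "y"), index, charge = 1L,
                        carbamidomethyl = TRUE) {
  series <- match.arg(series)
  n <- nchar(sequence)
  if (index < 1L || index > n - 1L) {
    abort(sprintf("fragment index %d out of range for a %d-residue peptide (1..%d)",
                  index, n, n - 1L))
  }
  sub <- if (series == "b") substr(sequence, 1L, index)
         else substr(sequence, n - index + 1L, n)
  comp <- peptide_composition(sub, carbamidomethyl = carbamidomethyl)
  if (series == "b") comp <- comp - WATER_COMPOSITION
  ion_mz(monoisotopic_mass(comp), charge)
}

# isotope-offset probability vector for one element (index 1 = offset 0)
.element_offsets <- function(element, max_offset) {
  iso <- isotope_table()
  rows <- iso[iso$element == element, ]
  if (!nrow(rows)) {
    abort(paste0("element not in the bundled isotope table: ", element))
  }
  off <- rows$nucleons - min(rows$nucleons)
  p <- numeric(max_offset + 1L)
  keep <- off <= max_offset
  p[off[keep] + 1L] <- rows$abundance[keep]
  p
}

# truncated convolution of two offset-probability vectors
.conv_trunc <- function(a, b) {
  n <- length(a)
  out <- numeric(n)
  for (k in seq_len(n)) {
    out[k] <- sum(a[seq_len(k)] * b[k:1])
  }
  out
}

# p convolved with itself n times, truncated (binary exponentiation)
.conv_pow <- function(p, n, len) {
  acc <- c(1, numeric(len - 1L))
  base <- p[seq_len(len)]
  while (n > 0L) {
    if (n %% 2L == 1L) acc <- .conv_trunc(acc, base)
    base <- .conv_trunc(base, base)
    n <- n %/% 2L
  }
  acc
}

#' Aggregated isotope envelope of an ion
#'
#' Computes the unit-mass-binned (aggregated) isotope distribution of a
#' composition by iterative convolution of per-element isotope patterns, then
#' truncates to at most `max_peaks` consecutive peaks starting at the
#' monoisotopic peak, dropping trailing peaks whose fraction falls below
#' `min_fraction`. Abundance fractions are deliberately *not* renormalized
#' after truncation, so the retained total measures the truncation loss.
#'
#' Peak k is placed at `mono_mz + k * 1.00286864 / charge` (aggregate spacing),
#' matching unit-resolution instrument appearance; fine isotope structure is
#' out of scope.
#'
#' @inheritParams monoisotopic_mass
#' @param max_peaks Maximum number of isotope peaks retained (default 5).
#' @param charge Ion charge used to place peak m/z values (default 1).
#' @param min_fraction Trailing peaks below this fraction are dropped
#'   (default 1e-4).
#' @return A tibble with columns `mz` (strictly increasing) and `abundance`
#'   (fractions of the full distribution, summing to <= 1).
#' @export
#' @examples
#' isotope_envelope(peptide_composition("PEPTIDEK"), charge = 2)
isotope_envelope <- function(composition, max_peaks = 5L, charge = 1L,
                             min_fraction = 1e-4) {
  stopifnot(max_peaks >= 1L, charge >= 1L)
  composition <- composition[composition != 0]
  len <- as.integer(max_peaks) + 5L
  dist <- c(1, numeric(len - 1L))
  for (el in names(composition)) {
    p <- .element_offsets(el, len - 1L)
    dist <- .conv_trunc(dist, .conv_pow(p, as.integer(composition[[el]]), len))
  }
  frac <- dist[seq_len(max_peaks)]
  keep <- frac >= min_fraction
  n_keep <- if (any(keep)) max(which(keep)) else 1L
  frac <- frac[seq_len(n_keep)]
  mono <- ion_mz(monoisotopic_mass(composition), charge)
  tibble::tibble(
    mz = mono + (seq_len(n_keep) - 1L) * NEUTRON_MASS_DELTA / charge,
    abundance = frac
  )
}
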