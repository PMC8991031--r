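# Forward model of peptide isotope envelopes: natural-abundance envelopes,
# deuterium-enriched plateau envelopes at a given precursor enrichment, and
# the expected M0 time course under first-order turnover.

# Terrestrial isotope abundances by nominal mass shift (0, +1, +2, ...).
# Fixed constants so envelopes are deterministic across platforms; printed in
# ?natural_envelope. S +3 has no stable isotope (36S sits at +4).
.isotope_patterns <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0.0, 0.0001)
)

# Monoisotopic masses (Da) of the light isotopes, plus water.
.mono_mass <- c(
  C = 12.0, H = 1.0078250319, N = 14.0030740052,
  O = 15.9949146221, S = 31.97207069
)
.water_mass <- 18.0105646863

.elements <- c("C", "H", "N", "O", "S")

#' Per-residue elemental formulas and exchangeable-hydrogen counts
#'
#' Reads the residue table shipped with the package (or a user-supplied CSV
#' with the same columns: \code{residue, C, H, N, O, S, exchangeable_H}).
#' The exchangeable-hydrogen column gives the number of carbon-bound hydrogen
#' sites per residue that equilibrate with body water during biosynthesis;
#' the shipped values are the standard literature MIDA values. They are an
#' explicit input so that downstream results are reproducible bit-for-bit
#' given a configuration.
#'
#' @param path CSV path; default is the table shipped under
#'   \code{inst/extdata/residue_formulas.csv}.
#' @return data.frame with one row per standard amino-acid residue.
#' @export
residue_table <- function(path = system.file("extdata", "residue_formulas.csv",
                                             package = "heavywater")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("residue", .elements, "exchangeable_H")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("residue table is missing column(s): ", paste(missing, collapse = ", "))
  }
  tab
}

#' Elemental composition of a tryptic peptide
#'
#' Sums per-residue formulas and adds one terminal water. Only the 20
#' standard one-letter codes are accepted.
#'
#' @param sequence amino-acid string, e.g. \code{"ASYSAVSLYGNPVR"}.
#' @param residues residue table (see [residue_table()]).
#' @return named integer vector with counts of C, H, N, O, S
#'   (class \code{"elemental_composition"}).
#' @export
composition_of_peptide <- function(sequence, residues = residue_table()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("empty peptide sequence")
  aa <- strsplit(sequence, "")[[1]]
  idx <- match(aa, residues$residue)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("unknown residue '%s' at position %d in '%s'",
                 aa[bad], bad, sequence))
  }
  counts <- colSums(residues[idx, .elements, drop = FALSE])
  counts <- as.integer(counts)
  names(counts) <- .elements
  counts["H"] <- counts["H"] + 2L  # terminal water
  counts["O"] <- counts["O"] + 1L
  structure(counts, class = "elemental_composition")
}

#' Number of deuterium-accessible hydrogen sites of a peptide
#'
#' @inheritParams composition_of_peptide
#' @return total exchangeable-hydrogen count (real, > 0 for nonempty peptide).
#' @export
exchangeable_hydrogens <- function(sequence, residues = residue_table()) {
  if (nchar(sequence) == 0L) stop("empty peptide sequence")
  aa <- strsplit(sequence, "")[[1]]
  idx <- match(aa, residues$residue)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("unknown residue '%s' at position %d", aa[bad], bad))
  }
  sum(residues$exchangeable_H[idx])
}

#' Monoisotopic mass of an elemental composition
#'
#' @param comp result of [composition_of_peptide()].
#' @return mass in Da.
#' @export
monoisotopic_mass <- function(comp) {
  sum(unclass(comp)[.elements] * .mono_mass[.elements])
}

# Truncated linear convolution of two abundance vectors; keeps indices
# 0..(len-1). Mass only moves upward, so truncating intermediates at `len`
# leaves the first `len` entries of the final product exact.
.convolve_trunc <- function(a, b, len) {
  out <- numeric(len)
  for (i in seq_along(a)) {
    jmax <- min(length(b), len - i + 1L)
    if (jmax >= 1L) {
      out[i:(i + jmax - 1L)] <- out[i:(i + jmax - 1L)] + a[i] * b[seq_len(jmax)]
    }
  }
  out
}

# n-fold self-convolution by exponentiation-by-squaring.
.convolve_power <- function(pattern, n, len) {
  result <- c(1, numeric(len - 1L))
  base <- c(pattern, numeric(max(0L, len - length(pattern))))[seq_len(len)]
  while (n > 0L) {
    if (n %% 2L == 1L) result <- .convolve_trunc(result, base, len)
    base <- .convolve_trunc(base, base, len)
    n <- n %/% 2L
  }
  result
}

# Unnormalized envelope (first `len` exact probabilities) for arbitrary
# per-element patterns. `h_split` optionally replaces the H channel with two
# sub-channels (counts + patterns) for enriched-site modelling.
.raw_envelope <- function(comp, len, h_split = NULL) {
  counts <- unclass(comp)
  env <- c(1, numeric(len - 1L))
  for (el in .elements) {
    n <- counts[[el]]
    if (el == "H" && !is.null(h_split)) next
    if (n > 0L) env <- .convolve_trunc(env, .convolve_power(.isotope_patterns[[el]], n, len), len)
  }
  if (!is.null(h_split)) {
    for (ch in h_split) {
      if (ch$n > 0L) env <- .convolve_trunc(env, .convolve_power(ch$pattern, ch$n, len), len)
    }
  }
  env
}

.as_envelope <- function(raw, n_peaks, max_tail = NULL) {
  kept <- sum(raw)
  tail_mass <- 1 - kept
  if (!is.null(max_tail) && tail_mass > max_tail) {
    warning(sprintf("truncated tail mass %.3g exceeds %.3g; increase n_peaks",
                    tail_mass, max_tail))
  }
  structure(raw / kept,
            tail_mass = tail_mass,
            names = paste0("M", seq_along(raw) - 1L),
            class = "isotopomer_envelope")
}

#' Natural-abundance isotope envelope
#'
#' Relative abundances of the M0..M(n_peaks-1) isotope peaks of a peptide at
#' terrestrial natural abundance, computed as the convolution of per-element
#' isotope patterns, truncated to \code{n_peaks} and renormalized to sum to 1.
#' The tracked probabilities are exact before renormalization (convolution
#' only moves mass upward, so truncating intermediates cannot corrupt the
#' kept peaks); the dropped tail mass is reported as an attribute and a
#' warning is raised if the tracked window misses more than 5\% of the
#' envelope.
#' Abundances used: 13C 1.07\%, 2H 0.0115\%, 15N 0.364\%, 17O 0.038\%,
#' 18O 0.205\%, 33S 0.75\%, 34S 4.25\%, 36S 0.01\%.
#'
#' @param comp an \code{elemental_composition}.
#' @param n_peaks number of tracked peaks (default 5: M0..M+4).
#' @return numeric vector of length \code{n_peaks} summing to 1, with the
#'   dropped tail mass in \code{attr(, "tail_mass")}.
#' @export
natural_envelope <- function(comp, n_peaks = 5L) {
  stopifnot(n_peaks >= 1L)
  counts <- unclass(comp)
  if (any(counts < 0)) stop("negative element count")
  if (sum(counts) == 0) stop("all-zero elemental composition")
  .as_envelope(.raw_envelope(comp, as.integer(n_peaks)), n_peaks, max_tail = 0.05)
}

# Integer-site labeled envelope: n_ex of the H sites carry heavy probability
# (natural 2H + p), the rest stay natural.
.labeled_envelope_int <- function(comp, n_ex, p, n_peaks) {
  h_total <- unclass(comp)[["H"]]
  p_heavy <- .isotope_patterns$H[2] + p
  h_split <- list(
    list(n = h_total - n_ex, pattern = .isotope_patterns$H),
    list(n = n_ex, pattern = c(1 - p_heavy, p_heavy))
  )
  .raw_envelope(comp, n_peaks, h_split = h_split)
}

#' Deuterium-enriched plateau envelope
#'
#' Envelope of a peptide synthesized entirely at body-water enrichment
#' \code{p}: the \code{n_exchangeable} deuterium-accessible hydrogen sites
#' carry heavy-isotope probability (natural 2H abundance + \code{p}); all
#' remaining hydrogens and other elements keep natural abundances.
#' Non-integer site counts are handled by linear interpolation between the
#' envelopes at the two neighbouring integer counts.
#'
#' @inheritParams natural_envelope
#' @param n_exchangeable deuterium-accessible hydrogen sites (real,
#'   0 <= n <= total H).
#' @param p precursor (body water) deuterium mole fraction, in [0, 0.2).
#' @return envelope as in [natural_envelope()].
#' @export
labeled_envelope <- function(comp, n_exchangeable, p, n_peaks = 5L) {
  stopifnot(n_peaks >= 1L)
  if (p < 0 || p >= 0.2) stop("precursor enrichment p must be in [0, 0.2)")
  h_total <- unclass(comp)[["H"]]
  if (n_exchangeable < 0 || n_exchangeable > h_total) {
    stop("n_exchangeable must lie in [0, total H]")
  }
  n_peaks <- as.integer(n_peaks)
  lo <- floor(n_exchangeable)
  hi <- ceiling(n_exchangeable)
  raw <- if (lo == hi) {
    .labeled_envelope_int(comp, as.integer(lo), p, n_peaks)
  } else {
    w <- n_exchangeable - lo
    (1 - w) * .labeled_envelope_int(comp, as.integer(lo), p, n_peaks) +
      w * .labeled_envelope_int(comp, as.integer(hi), p, n_peaks)
  }
  .as_envelope(raw, n_peaks, max_tail = NULL)
}

#' Expected relative M0 abundance under first-order turnover
#'
#' First-order replacement of the unlabeled pool by label-plateau material:
#' \deqn{M_0(t) = M_{plateau} + (M_{nat} - M_{plateau}) e^{-kt}.}
#' At \code{t = ln(2)/k} the value is the exact midpoint of the natural and
#' plateau levels, which is the defining property of the half-life.
#'
#' @param t time in days (vectorized, >= 0).
#' @param k first-order rate constant (per day, >= 0).
#' @param M0_nat natural-abundance relative M0.
#' @param M0_plateau fully-labeled plateau relative M0
#'   (\code{0 <= M0_plateau <= M0_nat <= 1}).
#' @return expected relative M0 at each \code{t}.
#' @export
expected_M0 <- function(t, k, M0_nat, M0_plateau) {
  if (any(t < 0)) stop("negative labeling time")
  if (k < 0) stop("negative rate constant")
  if (!(M0_plateau <= M0_nat && M0_nat <= 1 && M0_plateau >= 0)) {
    stop("require 0 <= M0_plateau <= M0_nat <= 1")
  }
  M0_plateau + (M0_nat - M0_plateau) * exp(-k * t)
}
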