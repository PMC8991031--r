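# Independent oracles used across the suite. These deliberately avoid the
# package's convolution/fitting code paths: envelopes by exhaustive
# enumeration of isotopologues, BH by the hand-stepped procedure, Grubbs by
# the t-distribution critical-value formula, Welch by the closed-form
# textbook expressions.

# Published monoisotopic residue masses (Da), frozen from a standard
# residue-mass table, for checking compositions by independent summation.
RESIDUE_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)
WATER_MONO_MASS <- 18.01056

# Exhaustive-enumeration envelope oracle: enumerate every combination of
# heavy-isotope counts per element (feasible for <= ~20 atoms), accumulate
# multinomial probabilities by total nominal mass shift, truncate to
# n_peaks, renormalize. Patterns are the same physical constants the package
# documents, written independently here.
ORACLE_PATTERNS <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0.0, 0.0001)
)

# probability that n atoms with isotope pattern pat produce total shift s,
# by explicit enumeration of per-isotope counts (multinomial)
.oracle_element_dist <- function(n, pat) {
  shifts <- seq_along(pat) - 1L
  if (n == 0) return(c(1))
  counts <- expand.grid(rep(list(0:n), length(pat)))
  counts <- counts[rowSums(counts) == n, , drop = FALSE]
  maxs <- n * max(shifts)
  out <- numeric(maxs + 1L)
  for (i in seq_len(nrow(counts))) {
    k <- as.numeric(counts[i, ])
    if (any(k > 0 & pat == 0)) next
    s <- sum(k * shifts)
    logp <- lgamma(n + 1) - sum(lgamma(k + 1)) +
      sum(ifelse(k > 0, k * log(pat), 0))
    out[s + 1L] <- out[s + 1L] + exp(logp)
  }
  out
}

oracle_envelope <- function(counts, n_peaks, patterns = ORACLE_PATTERNS) {
  dist <- c(1)
  for (el in names(patterns)) {
    n <- counts[[el]]
    if (is.null(n) || n == 0) next
    d <- .oracle_element_dist(n, patterns[[el]])
    new <- numeric(length(dist) + length(d) - 1L)
    for (i in seq_along(dist)) {
      new[i:(i + length(d) - 1L)] <- new[i:(i + length(d) - 1L)] + dist[i] * d
    }
    dist <- new
  }
  kept <- dist[seq_len(min(n_peaks, length(dist)))]
  kept <- c(kept, numeric(n_peaks - length(kept)))
  kept / sum(kept)
}

# Labeled-envelope oracle: H channel split into an enriched part (integer
# n_ex sites at natural 2H + p) and a natural remainder.
oracle_labeled_envelope <- function(counts, n_ex, p, n_peaks) {
  pats <- ORACLE_PATTERNS
  pats$H <- NULL
  ph <- 0.000115 + p
  pats$Hnat <- ORACLE_PATTERNS$H
  pats$Henr <- c(1 - ph, ph)
  counts$Hnat <- counts$H - n_ex
  counts$Henr <- n_ex
  counts$H <- NULL
  oracle_envelope(counts, n_peaks, patterns = pats)
}

# Hand-stepped Benjamini-Hochberg: largest k with p_(k) <= k q / m, flag all
# p <= p_(k).
oracle_bh <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= seq_len(m) * q / m)
  if (length(ok) == 0) return(rep(FALSE, m))
  p <= ps[max(ok)]
}

# Textbook two-sided Grubbs decision for the most extreme value.
oracle_grubbs_rejects <- function(x, alpha) {
  n <- length(x)
  g <- max(abs(x - mean(x))) / sd(x)
  tc <- qt(1 - alpha / (2 * n), df = n - 2)
  gcrit <- (n - 1) / sqrt(n) * sqrt(tc^2 / (n - 2 + tc^2))
  g > gcrit
}

# Closed-form Welch statistics.
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se <- sqrt(vx / nx + vy / ny)
  t <- (mean(x) - mean(y)) / se
  df <- (vx / nx + vy / ny)^2 /
    ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df), se = se)
}

# Small fast noise-free study shared by pipeline tests.
tiny_config <- function(noise = list(area_cv = 0, ratio_sd = 0, serum_cv = 0)) {
  proteins <- data.frame(
    protein = c("FASTP", "FASTP", "SLOWP", "SLOWP", "NOSYN", "NOSYN"),
    peptide = c("ASYSAVSLYGNPVR", "LVEVNPK", "TSYAELLGR", "AGFDPLVK",
                "GPAGPSGPAGK", "ELHLDNNK")
  )
  truth <- rbind(
    data.frame(protein = "FASTP", group = c("25wk", "90wk"),
               conc_pmol_mg = c(100, 200), k_per_d = c(0.021, 0.012)),
    data.frame(protein = "SLOWP", group = c("25wk", "90wk"),
               conc_pmol_mg = c(400, 300), k_per_d = c(0.005, 0.003)),
    data.frame(protein = "NOSYN", group = c("25wk", "90wk"),
               conc_pmol_mg = c(600, 350), k_per_d = c(0, 0))
  )
  groups <- data.frame(group = rep(c("25wk", "90wk"), each = 4),
                       duration_d = rep(c(15, 30, 45, 60), 2),
                       n_animals = rep(c(3, 2), each = 4))
  study_config(groups = groups, proteins = proteins, truth = truth,
               noise = noise)
}
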