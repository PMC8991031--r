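# Per-peptide synthesis rate constants from M0 time courses, Grubbs outlier
# filtering across peptides, protein-level aggregation with pooled SD, and
# half-life conversion.

#' Fit a first-order rate constant to a peptide M0 time course
#'
#' Nonlinear least squares of [expected_M0()] against observed relative M0
#' abundances, with k bounded in \code{[0, k_max]} per day. A series flat at
#' natural abundance yields k = 0 and is flagged not measurable. A protein is
#' called measurable only when the fitted total M0 decline over the observed
#' window exceeds 3x the residual SD of the fit (guards against implausibly
#' long half-lives derived from slight M0 reductions).
#'
#' @param days labeling duration of each observation (days; at least 2
#'   distinct positive durations).
#' @param M0 observed relative M0 abundance per observation, in [0, 1].
#' @param M0_nat natural-abundance relative M0 (anchor at t = 0).
#' @param M0_plateau fully-labeled plateau relative M0 (< M0_nat).
#' @param k_max upper bound for k (default 2/day).
#' @return list with \code{k}, \code{k_se}, \code{residual_sd}, \code{n_obs},
#'   \code{df}, \code{converged}, \code{measurable}, \code{fitted_decline}.
#' @export
fit_peptide_k <- function(days, M0, M0_nat, M0_plateau, k_max = 2) {
  stopifnot(length(days) == length(M0))
  if (!(M0_plateau < M0_nat)) stop("require M0_plateau < M0_nat")
  labeled <- days > 0
  if (length(unique(days[labeled])) < 2L) {
    stop("degenerate time course: need at least 2 distinct labeled durations")
  }
  dat <- data.frame(t = days, y = M0)

  # start from the log-linearized decline, guarded for flat series
  span <- M0_nat - M0_plateau
  z <- (dat$y - M0_plateau) / span
  ok <- labeled & z > 1e-9 & z < 1
  k_start <- if (any(ok)) stats::median(-log(z[ok]) / dat$t[ok]) else 1e-4
  k_start <- min(max(k_start, 1e-6), k_max - 1e-6)

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ expected_M0(t, k, M0_nat, M0_plateau),
                      data = dat, start = list(k = k_start),
                      lower = 0, upper = k_max,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  n <- nrow(dat)
  if (is.null(fit)) {
    # fall back to golden-section minimization of the SSE in k
    sse <- function(k) sum((dat$y - expected_M0(dat$t, k, M0_nat, M0_plateau))^2)
    opt <- stats::optimize(sse, c(0, k_max), tol = 1e-12)
    k_hat <- opt$minimum
    if (sse(0) <= opt$objective) k_hat <- 0
    rsd <- sqrt(sse(k_hat) / max(1L, n - 1L))
    k_se <- NA_real_
    converged <- FALSE
  } else {
    k_hat <- stats::coef(fit)[["k"]]
    rsd <- summary(fit)$sigma
    k_se <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                     error = function(e) NA_real_)
    converged <- TRUE
  }
  decline <- M0_nat - expected_M0(max(dat$t), k_hat, M0_nat, M0_plateau)
  measurable <- decline > 3 * rsd && decline > 0
  list(k = k_hat, k_se = k_se, residual_sd = rsd, n_obs = n,
       df = n - 1L, converged = converged, measurable = measurable,
       fitted_decline = decline)
}

# Two-sided Grubbs critical value for sample size n at significance alpha.
grubbs_critical <- function(n, alpha = 0.05) {
  tc <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  (n - 1) / sqrt(n) * sqrt(tc^2 / (n - 2 + tc^2))
}

#' Iterative two-sided Grubbs outlier filter
#'
#' Removes at most one value per iteration (the most extreme deviation from
#' the mean) while the Grubbs statistic exceeds the two-sided critical value,
#' stopping when no value is rejected or fewer than 3 values remain. With
#' fewer than 3 input values no test is performed and all are retained with a
#' warning.
#'
#' @param values numeric vector (e.g. per-peptide rate constants).
#' @param alpha significance level in (0, 0.5); default 0.05.
#' @return list with \code{retained}, \code{removed}, \code{n_removed}.
#' @export
grubbs_filter <- function(values, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 0.5)
  values <- values[order(values)]  # order-invariant output
  removed <- numeric(0)
  if (length(values) < 3L) {
    warning("fewer than 3 values: Grubbs test not performed, all retained")
    return(list(retained = values, removed = removed, n_removed = 0L))
  }
  repeat {
    n <- length(values)
    if (n < 3L) break
    dev <- abs(values - mean(values))
    s <- stats::sd(values)
    if (s < .Machine$double.eps) break
    g <- max(dev) / s
    if (g > grubbs_critical(n, alpha)) {
      drop <- which.max(dev)
      removed <- c(removed, values[drop])
      values <- values[-drop]
    } else break
  }
  list(retained = values, removed = removed, n_removed = length(removed))
}

#' Aggregate peptide rate fits to a protein-level kinetic result
#'
#' Protein k is the mean of the retained peptide rate constants; the pooled
#' SD is the square root of the degrees-of-freedom-weighted mean of the
#' per-peptide residual variances. A protein with no measurable peptide is
#' flagged not measurable (rendered as a dash in output tables).
#'
#' @param fits list of results from [fit_peptide_k()] (after any Grubbs
#'   filtering of their k values).
#' @return list with \code{k}, \code{pooled_sd}, \code{n_peptides},
#'   \code{half_life_d}, \code{half_life_yr}, \code{measurable}.
#' @export
aggregate_protein <- function(fits) {
  if (length(fits) == 0L) stop("no peptide fits to aggregate")
  k <- vapply(fits, `[[`, numeric(1), "k")
  s <- vapply(fits, `[[`, numeric(1), "residual_sd")
  df <- vapply(fits, `[[`, numeric(1), "df")
  meas <- vapply(fits, `[[`, logical(1), "measurable")
  pooled <- sqrt(sum(df * s^2) / sum(df))
  k_mean <- mean(k)
  measurable <- any(meas)
  hl <- half_life(if (measurable) k_mean else 0)
  list(k = k_mean, pooled_sd = pooled, n_peptides = length(fits),
       half_life_d = hl, half_life_yr = if (is.na(hl)) NA_real_ else days_to_years(hl),
       measurable = measurable)
}

#' Half-life from a first-order rate constant
#'
#' \code{ln(2)/k} in days. A zero (or negative, or missing) rate constant is
#' not measurable and returns NA, the sentinel rendered as a dash in output
#' tables — never infinity.
#'
#' @param k rate constant (per day), vectorized.
#' @return half-life in days, NA where not measurable.
#' @export
half_life <- function(k) {
  out <- ifelse(is.na(k) | k <= 0, NA_real_, log(2) / k)
  as.numeric(out)
}

#' Convert days to years at 3 significant figures
#'
#' @param d days (>= 0), vectorized.
#' @return years (d / 365), rounded to 3 significant figures.
#' @export
days_to_years <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("negative duration")
  signif(d / 365, 3)
}
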