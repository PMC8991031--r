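# Age-group comparison layer: Welch t-tests, Benjamini-Hochberg flags, and
# the fold/difference inversion identities used to reconstruct group means
# from printed comparison tables.

#' Welch two-sample t-test
#'
#' Two-tailed unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom. The reported difference is \code{mean(x) - mean(y)}; the 95\% CI
#' is \code{difference +/- t_crit(df, 0.975) * SE}.
#'
#' @param x,y numeric samples, each with n >= 2 and nonzero variance overall.
#' @return list with \code{t}, \code{df}, \code{p}, \code{diff}, \code{ci},
#'   \code{mean_x}, \code{mean_y}.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs at least 2 observations")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE, conf.level = 0.95)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, diff = mean(x) - mean(y),
       ci = as.numeric(ht$conf.int),
       mean_x = mean(x), mean_y = mean(y))
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up FDR procedure: flags every p-value at or below the largest
#' p_(k) with p_(k) <= k q / m.
#'
#' @param pvalues numeric vector in [0, 1] (NA allowed, never flagged).
#' @param q FDR level (default 0.05).
#' @return logical vector of flags, same order as input.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  flags <- rep(FALSE, length(pvalues))
  flags[ok] <- stats::p.adjust(pvalues[ok], method = "BH") <= q
  flags
}

#' Recover group means from a fold-change and mean difference
#'
#' Inverts the identities \code{mean_b = fold * mean_a} and
#' \code{mean_b - mean_a = diff} (with b:a the fold direction, e.g.
#' old:young): \code{mean_a = diff / (fold - 1)}.
#'
#' @param fold ratio of group b to group a (!= 1).
#' @param diff mean difference b - a, in the units of the means.
#' @return named numeric vector \code{c(mean_a, mean_b)}.
#' @export
invert_comparison <- function(fold, diff) {
  if (fold == 1) stop("fold = 1 leaves the means unidentified (singular)")
  mean_a <- diff / (fold - 1)
  c(mean_a = mean_a, mean_b = fold * mean_a)
}

#' Compare two groups across proteins with BH flags
#'
#' Applies [welch_t()] per protein to per-replicate values and flags
#' significance with [bh_fdr()] within the table family. Difference
#' convention: \code{group_b - group_a}.
#'
#' @param values data.frame with columns \code{protein}, \code{group},
#'   \code{value}.
#' @param group_a,group_b group labels; the difference is b - a.
#' @param q FDR level for BH flags.
#' @return data.frame with one row per protein: means, fold (b:a),
#'   difference, CI, t, df, p, bh_significant.
#' @export
compare_groups <- function(values, group_a, group_b, q = 0.05) {
  stopifnot(all(c("protein", "group", "value") %in% names(values)))
  proteins <- unique(values$protein)
  rows <- lapply(proteins, function(pr) {
    va <- values$value[values$protein == pr & values$group == group_a]
    vb <- values$value[values$protein == pr & values$group == group_b]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (length(va) < 2L || length(vb) < 2L ||
        (stats::sd(va) < 1e-15 && stats::sd(vb) < 1e-15)) {
      return(data.frame(protein = pr, mean_a = mean(va), mean_b = mean(vb),
                        fold = NA_real_, diff = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_,
                        t = NA_real_, df = NA_real_, p = NA_real_))
    }
    w <- tryCatch(welch_t(vb, va), error = function(e) NULL)
    if (is.null(w)) {
      return(data.frame(protein = pr, mean_a = mean(va), mean_b = mean(vb),
                        fold = if (mean(va) > 0) mean(vb) / mean(va) else NA_real_,
                        diff = mean(vb) - mean(va),
                        ci_lo = NA_real_, ci_hi = NA_real_,
                        t = NA_real_, df = NA_real_, p = NA_real_))
    }
    data.frame(protein = pr, mean_a = mean(va), mean_b = mean(vb),
               fold = if (mean(va) > 0) mean(vb) / mean(va) else NA_real_,
               diff = w$diff, ci_lo = w$ci[1], ci_hi = w$ci[2],
               t = w$t, df = w$df, p = w$p)
  })
  out <- do.call(rbind, rows)
  out$bh_significant <- bh_fdr(out$p, q = q)
  out
}
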