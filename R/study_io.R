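# Table readers with row-level validation, the end-to-end pipeline, and
# report rendering. CSV dialect: UTF-8, comma-separated, header row, long
# format, one observation per row; scale factors are separate columns, never
# embedded in strings.

.read_validated <- function(path, required, numeric_cols, check_row) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  for (cl in numeric_cols) tab[[cl]] <- suppressWarnings(as.numeric(tab[[cl]]))
  bad <- which(!vapply(seq_len(nrow(tab)), function(i) check_row(tab[i, ]),
                       logical(1)))
  errors <- if (length(bad) > 0) {
    sprintf("row %d: invalid values (%s)", bad,
            vapply(bad, function(i) paste(utils::capture.output(
              print(tab[i, required])), collapse = " "), character(1)))
  } else character(0)
  if (length(bad) > 0) tab <- tab[-bad, , drop = FALSE]
  attr(tab, "row_errors") <- errors
  tab
}

#' Read a long-format peptide isotopomer area table
#'
#' Required columns: \code{protein, peptide, animal_id, age_group,
#' label_days, isotopomer_index, area}. Rows with non-numeric or negative
#' areas, negative days, or negative isotopomer indices are dropped and
#' reported with line context in \code{attr(, "row_errors")}.
#'
#' @param path CSV path.
#' @return validated data.frame of records.
#' @export
read_peptide_table <- function(path) {
  .read_validated(
    path,
    required = c("protein", "peptide", "animal_id", "age_group",
                 "label_days", "isotopomer_index", "area"),
    numeric_cols = c("label_days", "isotopomer_index", "area"),
    check_row = function(r) {
      isTRUE(is.finite(r$area) && r$area >= 0 &&
               is.finite(r$label_days) && r$label_days >= 0 &&
               is.finite(r$isotopomer_index) && r$isotopomer_index >= 0)
    }
  )
}

#' Read a serum body-water enrichment table
#'
#' Required columns: \code{animal_id, age_group, day, enrichment}.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_serum_table <- function(path) {
  .read_validated(
    path,
    required = c("animal_id", "age_group", "day", "enrichment"),
    numeric_cols = c("day", "enrichment"),
    check_row = function(r) {
      isTRUE(is.finite(r$day) && r$day >= 0 &&
               is.finite(r$enrichment) && r$enrichment >= 0 && r$enrichment < 0.2)
    }
  )
}

#' Read a nucleic-acid isotopomer ratio table
#'
#' Required columns: \code{molecule, animal_id, age_group, label_days,
#' ratio}. Unlabeled standard rows are flagged by \code{label_days = 0}.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_nucleic_table <- function(path) {
  .read_validated(
    path,
    required = c("molecule", "animal_id", "age_group", "label_days", "ratio"),
    numeric_cols = c("label_days", "ratio"),
    check_row = function(r) {
      isTRUE(is.finite(r$ratio) && r$ratio >= 0 &&
               is.finite(r$label_days) && r$label_days >= 0)
    }
  )
}

.config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

.geomean <- function(x) exp(mean(log(x)))

#' Run the full labeling-study analysis
#'
#' Stages: precursor fit -> per-peptide M0 kinetics -> Grubbs filtering and
#' protein aggregation -> BSA-normalized concentration -> absolute synthesis
#' -> nucleic two-pool fits -> age-group comparisons with BH flags. Each
#' stage failure is reported with its stage label. Deterministic given
#' inputs and options.
#'
#' @param peptides peptide isotopomer table (data.frame or CSV path).
#' @param serum serum enrichment table (data.frame or CSV path).
#' @param nucleic nucleic ratio table (data.frame or CSV path), or NULL.
#' @param standards optional calibration standards (known_fraction, reading);
#'   when given, the serum \code{enrichment} column is treated as raw
#'   instrument readings and calibrated first.
#' @param fixed_p optional fixed precursor enrichment (e.g. 0.055); when NULL
#'   (default) the fitted cohort plateau is used downstream.
#' @param exclude_durations numeric vector of label durations dropped from
#'   the kinetic fits (e.g. 30 for an unusable dosing cohort).
#' @param concentration_mode \code{"all"} or \code{"top2"} peptides.
#' @param synthesis_mode \code{"multiply"} (conc x k) or \code{"divide"}
#'   (conc / half-life).
#' @param grubbs_alpha Grubbs significance level.
#' @param q BH FDR level.
#' @param bsa_protein protein id of the BSA internal-standard rows.
#' @param bsa_spike_pmol,protein_load_mg internal-standard constants.
#' @param nucleic_sites,nucleic_base_ratio derivative site count and natural
#'   base ratio for the fraction-new calibration; \code{nucleic_base_ratio =
#'   NULL} (default) estimates it from the unlabeled standard rows.
#' @param n_peaks tracked isotopomer peaks.
#' @return object of class \code{"d2o_report"}.
#' @export
run_pipeline <- function(peptides, serum, nucleic = NULL, standards = NULL,
                         fixed_p = NULL, exclude_durations = numeric(0),
                         concentration_mode = c("all", "top2"),
                         synthesis_mode = c("multiply", "divide"),
                         grubbs_alpha = 0.05, q = 0.05,
                         bsa_protein = "BSA_STD", bsa_spike_pmol = 8,
                         protein_load_mg = 0.05,
                         nucleic_sites = 4, nucleic_base_ratio = NULL,
                         n_peaks = 5L) {
  concentration_mode <- match.arg(concentration_mode)
  synthesis_mode <- match.arg(synthesis_mode)
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage: %s] %s", label, conditionMessage(e)), call. = FALSE)
    })
  }
  if (is.character(peptides)) peptides <- read_peptide_table(peptides)
  if (is.character(serum)) serum <- read_serum_table(serum)
  if (is.character(nucleic) && !is.null(nucleic)) nucleic <- read_nucleic_table(nucleic)

  log_counts <- list()

  # --- precursor -----------------------------------------------------------
  precursor <- stage("precursor", {
    enr <- serum$enrichment
    if (!is.null(standards)) enr <- calibrate_enrichment(enr, standards)
    fit_precursor(serum$day, enr)
  })
  p_hat <- if (!is.null(fixed_p)) fixed_p else precursor$p_max

  # --- peptide M0 series ---------------------------------------------------
  pep <- peptides[peptides$protein != bsa_protein, ]
  res <- residue_table()
  key <- interaction(pep$protein, pep$peptide, pep$animal_id, drop = TRUE)
  m0tab <- stage("relative M0", {
    do.call(rbind, lapply(split(pep, key), function(d) {
      d <- d[order(d$isotopomer_index), ]
      data.frame(protein = d$protein[1], peptide = d$peptide[1],
                 animal_id = d$animal_id[1], age_group = d$age_group[1],
                 label_days = d$label_days[1],
                 m0 = d$area[d$isotopomer_index == 0][1] / sum(d$area),
                 total_area = sum(d$area))
    }))
  })

  pep_ids <- unique(m0tab[c("protein", "peptide")])
  anchors <- stage("M0 anchors", {
    nat <- numeric(nrow(pep_ids)); plat <- numeric(nrow(pep_ids))
    for (i in seq_len(nrow(pep_ids))) {
      sq <- pep_ids$peptide[i]
      ctrl <- m0tab$m0[m0tab$peptide == sq & m0tab$protein == pep_ids$protein[i] &
                         m0tab$label_days == 0]
      comp <- composition_of_peptide(sq, residues = res)
      nat[i] <- if (length(ctrl) > 0) mean(ctrl) else
        unclass(natural_envelope(comp, n_peaks))[1]
      plat[i] <- unclass(labeled_envelope(comp, exchangeable_hydrogens(sq, res),
                                          p_hat, n_peaks))[1]
    }
    cbind(pep_ids, M0_nat = nat, M0_plateau = plat)
  })

  # --- peptide kinetics ----------------------------------------------------
  lab <- m0tab[m0tab$label_days > 0 &
                 !(m0tab$label_days %in% exclude_durations), ]
  groups <- unique(lab$age_group)
  peptide_fits <- stage("peptide kinetics", {
    rows <- list()
    for (g in groups) {
      for (i in seq_len(nrow(anchors))) {
        d <- lab[lab$age_group == g & lab$protein == anchors$protein[i] &
                   lab$peptide == anchors$peptide[i], ]
        if (length(unique(d$label_days)) < 2L) next
        ft <- fit_peptide_k(d$label_days, d$m0,
                            anchors$M0_nat[i], anchors$M0_plateau[i])
        rows[[length(rows) + 1L]] <- data.frame(
          protein = anchors$protein[i], peptide = anchors$peptide[i],
          age_group = g, k = ft$k, k_se = ft$k_se,
          residual_sd = ft$residual_sd, n_obs = ft$n_obs, df = ft$df,
          converged = ft$converged, measurable = ft$measurable)
      }
    }
    do.call(rbind, rows)
  })

  # --- Grubbs filter + protein aggregation ---------------------------------
  protein_kinetics <- stage("protein aggregation", {
    rows <- list(); removed_total <- 0L
    for (g in groups) {
      for (pr in unique(peptide_fits$protein)) {
        d <- peptide_fits[peptide_fits$protein == pr & peptide_fits$age_group == g, ]
        if (nrow(d) == 0) next
        keep <- rep(TRUE, nrow(d))
        if (nrow(d) >= 3) {
          gf <- grubbs_filter(d$k, alpha = grubbs_alpha)
          removed_total <- removed_total + gf$n_removed
          if (gf$n_removed > 0) {
            # drop one occurrence per removed value
            for (v in gf$removed) keep[which(keep & d$k == v)[1]] <- FALSE
          }
        }
        d <- d[keep, ]
        fits <- lapply(seq_len(nrow(d)), function(j) {
          list(k = d$k[j], residual_sd = d$residual_sd[j], df = d$df[j],
               measurable = d$measurable[j])
        })
        ag <- aggregate_protein(fits)
        rows[[length(rows) + 1L]] <- data.frame(
          protein = pr, age_group = g, k = ag$k, pooled_sd = ag$pooled_sd,
          n_peptides = ag$n_peptides, half_life_d = ag$half_life_d,
          half_life_yr = ag$half_life_yr, measurable = ag$measurable)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "grubbs_removed") <- removed_total
    out
  })
  log_counts$grubbs_removed <- attr(protein_kinetics, "grubbs_removed")

  # --- concentrations ------------------------------------------------------
  bsa_rows <- peptides[peptides$protein == bsa_protein, ]
  concentrations <- stage("concentration", {
    if (nrow(bsa_rows) == 0) stop("no BSA internal-standard rows found")
    bsa_area <- vapply(split(bsa_rows$area, bsa_rows$animal_id), sum, numeric(1))
    rows <- list()
    tot <- m0tab[m0tab$label_days > 0, ]
    for (an in unique(tot$animal_id)) {
      d <- tot[tot$animal_id == an, ]
      for (pr in unique(d$protein)) {
        areas <- d$total_area[d$protein == pr]
        cc <- concentration_from_internal_standard(
          areas, bsa_area[[an]], bsa_spike_pmol, protein_load_mg,
          mode = concentration_mode)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = an, age_group = d$age_group[1], protein = pr,
          concentration_pmol_mg = cc$concentration, n_peptides = cc$n_peptides)
      }
    }
    do.call(rbind, rows)
  })

  # --- absolute synthesis --------------------------------------------------
  absolute <- stage("absolute synthesis", {
    idx <- match(interaction(concentrations$protein, concentrations$age_group),
                 interaction(protein_kinetics$protein, protein_kinetics$age_group))
    k <- protein_kinetics$k[idx]
    meas <- protein_kinetics$measurable[idx]
    ok <- !is.na(k)
    out <- concentrations[ok, c("animal_id", "age_group", "protein")]
    asr <- absolute_synthesis(concentrations$concentration_pmol_mg[ok],
                              k[ok], meas[ok], mode = synthesis_mode)
    out$rate_pmol_mg_d <- asr$rate
    out$measurable <- asr$measurable
    out
  })

  # --- nucleic turnover ----------------------------------------------------
  nucleic_fits <- NULL
  if (!is.null(nucleic)) {
    nucleic_fits <- stage("nucleic turnover", {
      rows <- list(); clip_total <- 0L
      for (m in unique(nucleic$molecule)) {
        d <- nucleic[nucleic$molecule == m, ]
        base <- if (is.null(nucleic_base_ratio)) {
          std <- d$ratio[d$label_days == 0]
          if (length(std) == 0) stop("no unlabeled standard rows for ", m)
          mean(std)
        } else nucleic_base_ratio
        rmax <- max_ratio_for_precursor(p_hat, nucleic_sites, base)
        dl <- d[d$label_days > 0, ]
        for (g in unique(dl$age_group)) {
          dg <- dl[dl$age_group == g, ]
          f <- fraction_new(dg$ratio, base, rmax)
          clip_total <- clip_total + attr(f, "n_clipped")
          tp <- two_pool_fit(dg$label_days, as.numeric(f))
          rows[[length(rows) + 1L]] <- data.frame(
            molecule = m, age_group = g, F = tp$F,
            fast_halflife_upper_d = tp$fast_halflife_upper_d,
            slow_halflife_lower_d = tp$slow_halflife_lower_d,
            plateau = tp$plateau, n = nrow(dg))
        }
      }
      out <- do.call(rbind, rows)
      attr(out, "n_clipped") <- clip_total
      out
    })
    log_counts$fraction_new_clipped <- attr(nucleic_fits, "n_clipped")
  }

  # --- group comparisons ---------------------------------------------------
  comparisons <- NULL
  age_groups <- setdiff(groups, "unlabeled")
  if (length(age_groups) >= 2) {
    ga <- age_groups[1]; gb <- age_groups[2]
    comparisons <- stage("group statistics", {
      conc_vals <- data.frame(protein = concentrations$protein,
                              group = concentrations$age_group,
                              value = concentrations$concentration_pmol_mg)
      hl_vals <- data.frame(protein = peptide_fits$protein,
                            group = peptide_fits$age_group,
                            value = half_life(ifelse(peptide_fits$measurable,
                                                     peptide_fits$k, NA_real_)))
      abs_vals <- data.frame(protein = absolute$protein,
                             group = absolute$age_group,
                             value = absolute$rate_pmol_mg_d)
      list(concentration = compare_groups(conc_vals, ga, gb, q = q),
           half_life = compare_groups(hl_vals, ga, gb, q = q),
           absolute_synthesis = compare_groups(abs_vals, ga, gb, q = q),
           group_a = ga, group_b = gb)
    })
  }

  opts <- list(fixed_p = fixed_p, exclude_durations = exclude_durations,
               concentration_mode = concentration_mode,
               synthesis_mode = synthesis_mode, grubbs_alpha = grubbs_alpha,
               q = q, bsa_spike_pmol = bsa_spike_pmol,
               protein_load_mg = protein_load_mg,
               nucleic_sites = nucleic_sites, n_peaks = n_peaks)
  structure(list(precursor = precursor, p_used = p_hat,
                 peptide_fits = peptide_fits,
                 protein_kinetics = protein_kinetics,
                 concentrations = concentrations, absolute = absolute,
                 nucleic = nucleic_fits, comparisons = comparisons,
                 metadata = list(options = opts,
                                 config_hash = .config_hash(opts),
                                 counts = log_counts,
                                 version = as.character(utils::packageVersion("heavywater")))),
            class = "d2o_report")
}

#' Render protein kinetics with the dash convention
#'
#' Not-measurable half-lives print as \code{"-"}, never a number or
#' infinity.
#'
#' @param report a \code{d2o_report}.
#' @param digits significant digits for numeric columns.
#' @return character data.frame mirroring the protein kinetics table.
#' @export
render_kinetics <- function(report, digits = 3) {
  k <- report$protein_kinetics
  dash <- function(x, meas) ifelse(meas & !is.na(x),
                                   format(signif(x, digits)), "-")
  data.frame(protein = k$protein, age_group = k$age_group,
             n_peptides = k$n_peptides,
             k_per_d = dash(k$k, k$measurable),
             pooled_sd = format(signif(k$pooled_sd, digits)),
             half_life_d = dash(k$half_life_d, k$measurable),
             half_life_yr = dash(k$half_life_yr, k$measurable),
             stringsAsFactors = FALSE)
}

#' @export
print.d2o_report <- function(x, ...) {
  cat("D2O labeling study report\n")
  cat(sprintf("  precursor plateau: %.4f (p used downstream: %.4f)\n",
              x$precursor$p_max, x$p_used))
  cat(sprintf("  peptide fits: %d; proteins: %d\n",
              nrow(x$peptide_fits),
              length(unique(x$protein_kinetics$protein))))
  if (!is.null(x$nucleic)) {
    cat(sprintf("  nucleic fits: %d (fast-pool F range %.2f-%.2f)\n",
                nrow(x$nucleic), min(x$nucleic$F), max(x$nucleic$F)))
  }
  if (!is.null(x$comparisons)) {
    cat(sprintf("  comparisons: %s vs %s; BH-flagged concentrations: %d\n",
                x$comparisons$group_b, x$comparisons$group_a,
                sum(x$comparisons$concentration$bh_significant, na.rm = TRUE)))
  }
  cat(sprintf("  config hash: %s\n", x$metadata$config_hash))
  invisible(x)
}
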