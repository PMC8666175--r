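# Assay figures of merit: lower limits of detection and quantification,
# response-curve linearity, intra-/inter-assay and total CV, and the
# peptide acceptance filter. Conventions follow CPTAC assay-characterization
# practice: CVs are SD/mean on the ratio (not log) scale, in percent.

.cv_percent <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  100 * stats::sd(x) / m
}

#' Lower limit of detection from blank runs
#'
#' The detection threshold is the mean blank signal plus three times its
#' standard deviation. When no blank carries signal (all missing or zero),
#' the fallback threshold is three times the standard deviation of the
#' signal at the lowest spiked level. The threshold is mapped to
#' concentration through the calibration line and floored at zero.
#'
#' @param blank_areas Numeric vector of per-run blank signals (>= 3 runs).
#' @param lowest_spike_areas Signals at the lowest spiked level, used only
#'   on the fallback path.
#' @param calibration List with `slope` (> 0, area units per fmol) and
#'   `intercept` (default 0), the fitted signal response.
#' @return LLOD in fmol.
#' @export
compute_llod <- function(blank_areas, lowest_spike_areas = NULL,
                         calibration) {
  if (length(blank_areas) < 3) {
    stop("at least 3 blank runs are required", call. = FALSE)
  }
  slope <- calibration$slope
  intercept <- if (is.null(calibration$intercept)) 0 else calibration$intercept
  if (is.null(slope) || is.na(slope) || slope <= 0) {
    stop("degenerate calibration: slope must be positive", call. = FALSE)
  }
  usable <- blank_areas[!is.na(blank_areas)]
  if (length(usable) == 0 || all(usable == 0)) {
    if (is.null(lowest_spike_areas) || sum(!is.na(lowest_spike_areas)) < 2) {
      stop("no blank signal and insufficient lowest-spike signals for fallback",
           call. = FALSE)
    }
    threshold <- 3 * stats::sd(lowest_spike_areas, na.rm = TRUE)
  } else {
    if (length(usable) < 3) {
      stop("at least 3 non-missing blank signals are required", call. = FALSE)
    }
    threshold <- mean(usable) + 3 * stats::sd(usable)
  }
  max(0, (threshold - intercept) / slope)
}

#' Lower limit of quantification from per-level replicate CVs
#'
#' The LLOQ is the lowest spiked level at which the CV of the measured
#' signal is below `cv_threshold` percent and stays below it at every
#' higher level; this guards against non-monotone noise dips defining a
#' spurious LLOQ. Returns `NA` (not quantifiable) when no level qualifies.
#'
#' @param series Data frame with columns `level` (fmol) and `value`
#'   (replicate measurements, >= 2 per level).
#' @param cv_threshold CV acceptance threshold in percent (default 20).
#' @return List with `lloq_fmol` (NA when not quantifiable) and `cv_by_level`
#'   (named vector of per-level CVs in percent).
#' @export
compute_lloq <- function(series, cv_threshold = 20) {
  levels_sorted <- sort(unique(series$level))
  cvs <- vapply(levels_sorted, function(lv) {
    vals <- series$value[series$level == lv & !is.na(series$value)]
    if (length(vals) < 2) {
      stop("insufficient replicates (<2) at level ", lv, call. = FALSE)
    }
    .cv_percent(vals)
  }, numeric(1))
  names(cvs) <- as.character(levels_sorted)
  ok <- cvs < cv_threshold
  ok_above <- rev(cumprod(rev(ok))) == 1  # ok at level and all higher levels
  lloq <- if (any(ok_above)) levels_sorted[which(ok_above)[1]] else NA_real_
  list(lloq_fmol = lloq, cv_by_level = cvs)
}

#' Fit response-curve linearity
#'
#' Ordinary least squares of the mean measured ratio against the nominal
#' spike level. At protein scope the ratios of all monitored peptides are
#' first averaged per level, so the protein response is the mean peptide
#' response.
#'
#' @param series Data frame with columns `level`, `ratio`, and (for protein
#'   scope) `peptide`.
#' @param scope `"peptide"` or `"protein"`.
#' @return List with `slope`, `intercept`, `r_squared`, `n_levels`.
#' @export
fit_linearity <- function(series, scope = c("peptide", "protein")) {
  scope <- match.arg(scope)
  df <- series[!is.na(series$ratio), , drop = FALSE]
  if (scope == "protein") {
    if (!"peptide" %in% names(df)) {
      stop("protein scope requires a peptide column", call. = FALSE)
    }
    per_pep <- stats::aggregate(ratio ~ peptide + level, data = df, FUN = mean)
    df <- stats::aggregate(ratio ~ level, data = per_pep, FUN = mean)
  } else {
    df <- stats::aggregate(ratio ~ level, data = df, FUN = mean)
  }
  if (nrow(df) < 3) {
    stop("at least 3 distinct levels are required for a linearity fit",
         call. = FALSE)
  }
  fit <- stats::lm(ratio ~ level, data = df)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((df$ratio - mean(df$ratio))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, n_levels = nrow(df))
}

#' Intra-assay, inter-assay and total CV from a days-by-replicates design
#'
#' Intra-assay CV is the average over days of the CV of the within-day
#' replicates. Inter-assay CV is the average over replicate index of the CV
#' of that injection across days. Total CV combines them in quadrature:
#' `total = sqrt(intra^2 + inter^2)`.
#'
#' @param design_table Data frame with columns `day`, `replicate`, `value`.
#'   Missing cells are tolerated as long as >= 2 usable entries remain per
#'   averaged axis element.
#' @return Named numeric vector `c(intra_cv, inter_cv, total_cv)` in percent.
#' @export
compute_cv_components <- function(design_table) {
  df <- design_table[!is.na(design_table$value), , drop = FALSE]
  days <- unique(df$day)
  reps <- unique(df$replicate)
  if (length(days) < 2 || length(reps) < 2) {
    stop("need at least 2 usable days and 2 replicates", call. = FALSE)
  }
  day_cvs <- vapply(days, function(d) {
    .cv_percent(df$value[df$day == d])
  }, numeric(1))
  rep_cvs <- vapply(reps, function(r) {
    .cv_percent(df$value[df$replicate == r])
  }, numeric(1))
  if (sum(!is.na(day_cvs)) < 2 || sum(!is.na(rep_cvs)) < 2) {
    stop("insufficient data: fewer than 2 usable days or replicates",
         call. = FALSE)
  }
  intra <- mean(day_cvs, na.rm = TRUE)
  inter <- mean(rep_cvs, na.rm = TRUE)
  c(intra_cv = intra, inter_cv = inter,
    total_cv = sqrt(intra^2 + inter^2))
}

#' Apply the CV acceptance filter to an assay report
#'
#' A peptide is accepted when its intra-assay, inter-assay and total CVs are
#' all strictly below the threshold at every assayed level. Protein-level
#' total CV per level is the mean of the accepted peptides' total CVs.
#'
#' @param cv_table Data frame with columns `peptide`, `protein`, `level`,
#'   `intra_cv`, `inter_cv`, `total_cv` (percent).
#' @param threshold Acceptance threshold in percent (default 20).
#' @return List with `accepted` (character vector of peptides),
#'   `peptide_flags` (per-peptide logical), and `protein_cv` (data frame
#'   `protein`, `level`, `total_cv` over accepted peptides).
#' @export
accept_peptides <- function(cv_table, threshold = 20) {
  if (nrow(cv_table) == 0) {
    return(list(accepted = character(0),
                peptide_flags = stats::setNames(logical(0), character(0)),
                protein_cv = data.frame(protein = character(0),
                                        level = numeric(0),
                                        total_cv = numeric(0))))
  }
  ok_row <- with(cv_table, !is.na(intra_cv) & !is.na(inter_cv) &
                   !is.na(total_cv) & intra_cv < threshold &
                   inter_cv < threshold & total_cv < threshold)
  flags <- tapply(ok_row, cv_table$peptide, all)
  accepted <- names(flags)[flags]
  acc_rows <- cv_table[cv_table$peptide %in% accepted, , drop = FALSE]
  protein_cv <- if (nrow(acc_rows) > 0) {
    stats::aggregate(total_cv ~ protein + level, data = acc_rows, FUN = mean)
  } else {
    data.frame(protein = character(0), level = numeric(0),
               total_cv = numeric(0))
  }
  list(accepted = accepted,
       peptide_flags = stats::setNames(as.logical(flags), names(flags)),
       protein_cv = protein_cv)
}

#' Characterize a full assay from calibration and replicate-design data
#'
#' Runs the complete figure-of-merit workflow: per-peptide heavy/light
#' ratios over the dilution series, LLOD from blank runs through the fitted
#' signal response, LLOQ from per-level ratio CVs, linearity at peptide and
#' protein scope, CV components at each replicate-design level, and the CV
#' acceptance filter. A warning flag marks peptides whose LLOQ falls below
#' their LLOD (the two rules use different arithmetic and need not be
#' ordered).
#'
#' @param calibration List with `transitions` and `metadata` as produced by
#'   [generate_calibration()] or read from files.
#' @param replicate List with `transitions` and `metadata` from the
#'   replicate design.
#' @param cv_threshold Acceptance threshold in percent (default 20).
#' @param fold_tolerance Interference screening tolerance passed to
#'   [flag_interference()].
#' @return An [assay_report()] with per-peptide and per-protein tables.
#' @export
build_assay_report <- function(calibration, replicate, cv_threshold = 20,
                               fold_tolerance = 2) {
  cal_tr <- calibration$transitions
  cal_meta <- calibration$metadata
  excl <- flag_interference(cal_tr, fold_tolerance = fold_tolerance)
  ratios <- compute_ratios(cal_tr, excluded = excl,
                           orientation = "heavy_over_light")
  ratios <- merge(ratios, cal_meta[c("run_id", "run_type", "spike_fmol")],
                  by = "run_id")
  cal_ratios <- ratios[ratios$run_type == "calibration", , drop = FALSE]

  # per-run summed heavy signal per peptide (for LLOD)
  heavy <- cal_tr[cal_tr$label == "heavy" & !is.na(cal_tr$area), , drop = FALSE]
  heavy_sum <- stats::aggregate(area ~ run_id + peptide, data = heavy, FUN = sum)
  heavy_sum <- merge(heavy_sum, cal_meta[c("run_id", "run_type", "spike_fmol")],
                     by = "run_id")

  pep_prot <- unique(cal_tr[c("peptide", "protein")])
  peptides <- pep_prot$peptide
  lowest_level <- min(cal_meta$spike_fmol[cal_meta$run_type == "calibration"])

  pep_rows <- lapply(seq_along(peptides), function(i) {
    pep <- peptides[i]
    hs <- heavy_sum[heavy_sum$peptide == pep, , drop = FALSE]
    blanks <- hs$area[hs$run_type == "blank"]
    lowest <- hs$area[hs$run_type == "calibration" &
                        hs$spike_fmol == lowest_level]
    sig <- hs[hs$run_type == "calibration", , drop = FALSE]
    sig_fit <- stats::lm(area ~ spike_fmol, data = sig)
    calib <- list(slope = unname(stats::coef(sig_fit)[2]),
                  intercept = unname(stats::coef(sig_fit)[1]))
    llod <- tryCatch(compute_llod(blanks, lowest, calib),
                     error = function(e) NA_real_)
    pr <- cal_ratios[cal_ratios$peptide == pep, , drop = FALSE]
    lloq_in <- data.frame(level = pr$spike_fmol, value = pr$ratio)
    lloq <- tryCatch(compute_lloq(lloq_in, cv_threshold = cv_threshold),
                     error = function(e) list(lloq_fmol = NA_real_))
    lin <- tryCatch(fit_linearity(data.frame(level = pr$spike_fmol,
                                             ratio = pr$ratio),
                                  scope = "peptide"),
                    error = function(e) list(slope = NA_real_,
                                             r_squared = NA_real_))
    data.frame(peptide = pep, protein = pep_prot$protein[i],
               llod_fmol = llod, lloq_fmol = lloq$lloq_fmol,
               response_slope = lin$slope, r_squared = lin$r_squared,
               lloq_below_llod = isTRUE(!is.na(lloq$lloq_fmol) &&
                                          !is.na(llod) &&
                                          lloq$lloq_fmol < llod),
               stringsAsFactors = FALSE)
  })
  pep_df <- do.call(rbind, pep_rows)

  # replicate-design CV components on the heavy/light ratio per level
  rep_excl <- flag_interference(replicate$transitions,
                                fold_tolerance = fold_tolerance)
  rep_ratios <- compute_ratios(replicate$transitions, excluded = rep_excl,
                               orientation = "heavy_over_light")
  rep_ratios <- merge(rep_ratios,
                      replicate$metadata[c("run_id", "spike_fmol",
                                           "day_index", "replicate_index")],
                      by = "run_id")
  cv_rows <- list()
  for (pep in unique(rep_ratios$peptide)) {
    for (lv in sort(unique(rep_ratios$spike_fmol))) {
      sub <- rep_ratios[rep_ratios$peptide == pep &
                          rep_ratios$spike_fmol == lv, , drop = FALSE]
      comp <- tryCatch(
        compute_cv_components(data.frame(day = sub$day_index,
                                         replicate = sub$replicate_index,
                                         value = sub$ratio)),
        error = function(e) c(intra_cv = NA_real_, inter_cv = NA_real_,
                              total_cv = NA_real_))
      cv_rows[[length(cv_rows) + 1L]] <- data.frame(
        peptide = pep,
        protein = pep_prot$protein[match(pep, pep_prot$peptide)],
        level = lv, intra_cv = comp[["intra_cv"]],
        inter_cv = comp[["inter_cv"]], total_cv = comp[["total_cv"]],
        stringsAsFactors = FALSE
      )
    }
  }
  cv_df <- do.call(rbind, cv_rows)
  acc <- accept_peptides(cv_df, threshold = cv_threshold)
  pep_df$accepted <- pep_df$peptide %in% acc$accepted
  pep_df <- merge(pep_df,
                  stats::reshape(cv_df[c("peptide", "level", "total_cv")],
                                 idvar = "peptide", timevar = "level",
                                 v.names = "total_cv", direction = "wide"),
                  by = "peptide", all.x = TRUE)

  # per-protein linearity (average of peptide ratios per level) and CV
  prot_rows <- lapply(unique(pep_prot$protein), function(prot) {
    peps <- pep_prot$peptide[pep_prot$protein == prot]
    pr <- cal_ratios[cal_ratios$peptide %in% peps, , drop = FALSE]
    lin <- tryCatch(fit_linearity(data.frame(level = pr$spike_fmol,
                                             ratio = pr$ratio,
                                             peptide = pr$peptide),
                                  scope = "protein"),
                    error = function(e) list(r_squared = NA_real_))
    data.frame(protein = prot,
               protein_r_squared = lin$r_squared,
               llod_fmol = suppressWarnings(
                 max(pep_df$llod_fmol[pep_df$protein == prot], na.rm = TRUE)),
               lloq_fmol = suppressWarnings(
                 max(pep_df$lloq_fmol[pep_df$protein == prot], na.rm = TRUE)),
               stringsAsFactors = FALSE)
  })
  prot_df <- do.call(rbind, prot_rows)
  prot_df$llod_fmol[!is.finite(prot_df$llod_fmol)] <- NA_real_
  prot_df$lloq_fmol[!is.finite(prot_df$lloq_fmol)] <- NA_real_
  prot_df <- merge(prot_df,
                   stats::reshape(acc$protein_cv, idvar = "protein",
                                  timevar = "level", v.names = "total_cv",
                                  direction = "wide"),
                   by = "protein", all.x = TRUE)
  rep_obj <- assay_report(pep_df, prot_df)
  attr(rep_obj, "cv_table") <- cv_df
  rep_obj
}
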