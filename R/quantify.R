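# Transition-level ratio computation with automated interference screening,
# heavy-standard run normalization, and weighted peptide-to-protein rollup.

#' Screen transitions for interference
#'
#' Within each (run, peptide), each transition's light/heavy area ratio is
#' compared with the within-peptide median transition ratio. A transition
#' is flagged when its ratio deviates from the median by more than
#' `fold_tolerance` in either direction: co-eluting contaminants distort a
#' single transition's ratio while genuine signal keeps all transitions
#' proportional. At least one transition is always retained per peptide,
#' and single-transition peptides are returned unflagged with a warning.
#'
#' @param transitions Transition table ([transition_columns]) containing
#'   light and heavy rows for shared fragments.
#' @param fold_tolerance Maximum accepted fold deviation from the median
#'   transition ratio (default 2).
#' @return Data frame of excluded transitions: `run_id`, `peptide`,
#'   `fragment`, `reason`.
#' @export
flag_interference <- function(transitions, fold_tolerance = 2) {
  if (fold_tolerance <= 1) {
    stop("fold_tolerance must be greater than 1", call. = FALSE)
  }
  tr <- transitions[!is.na(transitions$area), , drop = FALSE]
  light <- tr[tr$label == "light", c("run_id", "peptide", "fragment", "area")]
  heavy <- tr[tr$label == "heavy", c("run_id", "peptide", "fragment", "area")]
  names(light)[4] <- "light_area"
  names(heavy)[4] <- "heavy_area"
  pairs <- merge(light, heavy, by = c("run_id", "peptide", "fragment"))
  pairs <- pairs[pairs$heavy_area > 0 & pairs$light_area > 0, , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(data.frame(run_id = character(0), peptide = character(0),
                      fragment = character(0), reason = character(0),
                      stringsAsFactors = FALSE))
  }
  pairs$ratio <- pairs$light_area / pairs$heavy_area
  out <- list()
  singles <- 0L
  key <- paste(pairs$run_id, pairs$peptide, sep = "\r")
  for (grp in split(pairs, key)) {
    if (nrow(grp) < 2) {
      singles <- singles + 1L
      next
    }
    med <- stats::median(grp$ratio)
    dev <- pmax(grp$ratio / med, med / grp$ratio)
    bad <- dev > fold_tolerance
    if (all(bad)) {
      # keep the transition closest to the median
      bad[which.min(dev)] <- FALSE
    }
    if (sum(!bad) == 0) bad[which.min(dev)] <- FALSE
    if (any(bad)) {
      out[[length(out) + 1L]] <- data.frame(
        run_id = grp$run_id[bad], peptide = grp$peptide[bad],
        fragment = grp$fragment[bad],
        reason = sprintf("ratio deviates %.2f-fold from median", dev[bad]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (singles > 0) {
    warning(singles, " (run, peptide) group(s) had a single usable ",
            "transition; interference screening skipped for them",
            call. = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(run_id = character(0), peptide = character(0),
                      fragment = character(0), reason = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Compute per-peptide light/heavy ratios from summed transition areas
#'
#' The peptide ratio in a run is the sum of usable light transition areas
#' divided by the sum of usable heavy transition areas (or the inverse for
#' calibration experiments that track the spiked heavy standard). Summing
#' before dividing weights transitions by their signal, making the ratio
#' robust to weak-transition noise.
#'
#' @param transitions Transition table.
#' @param excluded Optional exclusion set from [flag_interference()].
#' @param orientation `"light_over_heavy"` (endogenous over standard,
#'   default) or `"heavy_over_light"`.
#' @return Data frame per (run, peptide): `ratio`, `log2_ratio`,
#'   `transitions_used`, `transitions_excluded`, `reason` (NA unless the
#'   ratio is missing).
#' @export
compute_ratios <- function(transitions, excluded = NULL,
                           orientation = c("light_over_heavy",
                                           "heavy_over_light")) {
  orientation <- match.arg(orientation)
  tr <- transitions
  tr$excluded <- FALSE
  if (!is.null(excluded) && nrow(excluded) > 0) {
    key <- paste(tr$run_id, tr$peptide, tr$fragment, sep = "\r")
    ex_key <- paste(excluded$run_id, excluded$peptide, excluded$fragment,
                    sep = "\r")
    tr$excluded <- key %in% ex_key
  }
  groups <- split(tr, paste(tr$run_id, tr$peptide, sep = "\r"))
  rows <- lapply(groups, function(grp) {
    used <- grp[!grp$excluded, , drop = FALSE]
    light <- used$area[used$label == "light"]
    heavy <- used$area[used$label == "heavy"]
    light_sum <- sum(light, na.rm = TRUE)
    heavy_sum <- sum(heavy, na.rm = TRUE)
    n_frag <- length(unique(grp$fragment))
    n_used <- length(unique(used$fragment[!is.na(used$area)]))
    reason <- NA_character_
    ratio <- NA_real_
    if (all(is.na(light))) {
      reason <- "no_light_signal"
    } else if (all(is.na(heavy))) {
      reason <- "no_heavy_signal"
    } else {
      num <- if (orientation == "light_over_heavy") light_sum else heavy_sum
      den <- if (orientation == "light_over_heavy") heavy_sum else light_sum
      if (den == 0) {
        reason <- if (orientation == "light_over_heavy") {
          "zero_heavy_signal"
        } else {
          "zero_light_signal"
        }
      } else {
        ratio <- num / den
      }
    }
    data.frame(run_id = grp$run_id[1], peptide = grp$peptide[1],
               protein = grp$protein[1], ratio = ratio,
               log2_ratio = ifelse(is.na(ratio) || ratio <= 0,
                                   NA_real_, log2(ratio)),
               transitions_used = n_used,
               transitions_excluded = n_frag - n_used,
               reason = reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize peptide abundances against heavy-standard areas
#'
#' Heavy internal standards are spiked at a constant amount, so run-to-run
#' variation in their measured areas reflects technical factors (loading,
#' instrument response). The per-run technical factor is estimated as the
#' median over peptides of the run's log2 heavy area minus that peptide's
#' across-run mean log2 heavy area; subtracting it levels the heavy
#' standards across runs. Runs with fewer than 3 heavy observations keep a
#' factor of 0 and are flagged with a warning.
#'
#' @param values Data frame with columns `sample_id` (or `run_id`),
#'   `peptide`, `value` (log2 peptide abundance or log2 ratio).
#' @param heavy_areas Data frame with columns `sample_id`/`run_id`,
#'   `peptide`, `heavy_area` (> 0 linear-scale areas).
#' @param method `"median"` (robust median run-factor estimator, default) or
#'   `"least_squares"` (run effects from a two-way peptide + run linear
#'   model of the log2 heavy areas, centered to mean zero). The two agree
#'   on symmetric noise; the median is preferred for small panels where a
#'   few aberrant heavy measurements would leverage a least-squares fit.
#' @return List with `values` (input with `value` replaced by the
#'   normalized value), `factors` (data frame `sample_id`, `factor_log2`,
#'   `n_heavy`, `flagged`).
#' @export
normalize_runs <- function(values, heavy_areas,
                           method = c("median", "least_squares")) {
  method <- match.arg(method)
  id_col <- if ("sample_id" %in% names(values)) "sample_id" else "run_id"
  hv <- heavy_areas
  if (!(id_col %in% names(hv))) {
    names(hv)[names(hv) %in% c("sample_id", "run_id")] <- id_col
  }
  hv <- hv[!is.na(hv$heavy_area) & hv$heavy_area > 0, , drop = FALSE]
  hv$log2_heavy <- log2(hv$heavy_area)
  pep_means <- tapply(hv$log2_heavy, hv$peptide, mean)
  hv$centered <- hv$log2_heavy - pep_means[hv$peptide]
  runs <- unique(values[[id_col]])
  ls_fac <- NULL
  if (method == "least_squares" && length(unique(hv$peptide)) > 1) {
    df <- data.frame(y = hv$log2_heavy,
                     peptide = factor(hv$peptide),
                     run = factor(hv[[id_col]], levels = runs))
    fit <- stats::lm(y ~ peptide + run, data = df)
    co <- stats::coef(fit)
    eff <- stats::setNames(rep(NA_real_, length(runs)), runs)
    eff[levels(df$run)[1]] <- 0
    for (r in levels(df$run)[-1]) {
      eff[r] <- unname(co[paste0("run", r)])
    }
    ls_fac <- eff - mean(eff, na.rm = TRUE)
  }
  fac <- vapply(runs, function(r) {
    cc <- hv$centered[hv[[id_col]] == r]
    if (length(cc) < 3) return(NA_real_)
    if (!is.null(ls_fac)) ls_fac[[r]] else stats::median(cc)
  }, numeric(1))
  flagged <- is.na(fac)
  if (any(flagged)) {
    warning(sum(flagged), " run(s) had fewer than 3 heavy observations; ",
            "their normalization factor was set to 0", call. = FALSE)
    fac[flagged] <- 0
  }
  factors <- data.frame(sample_id = runs, factor_log2 = unname(fac),
                        n_heavy = vapply(runs, function(r) {
                          sum(hv[[id_col]] == r)
                        }, integer(1)),
                        flagged = unname(flagged),
                        stringsAsFactors = FALSE)
  out <- values
  out$value <- out$value - fac[match(out[[id_col]], runs)]
  list(values = out, factors = factors)
}

#' Roll peptide abundances up to protein estimators
#'
#' The protein abundance in a sample is a weighted sum of its peptides'
#' abundances with weights summing to 1 over the non-missing peptides.
#' Default weights are proportional to the inverse variance of each
#' peptide's values across samples (after centering per peptide), which is
#' the minimum-variance linear combination when peptide noise dominates;
#' an equal-weight scheme is available. A protein with no non-missing
#' peptide in a sample yields a missing cell.
#'
#' @param values Data frame with columns `sample_id`, `protein`, `peptide`,
#'   `value` (log2 abundance).
#' @param weights `"inverse_variance"` (default) or `"equal"`.
#' @return A [protein_matrix()] (samples x proteins) with per-protein
#'   peptide weights in its `provenance` attribute.
#' @export
rollup <- function(values, weights = c("inverse_variance", "equal")) {
  weights <- match.arg(weights)
  samples <- unique(values$sample_id)
  proteins <- unique(values$protein)
  mat <- matrix(NA_real_, length(samples), length(proteins),
                dimnames = list(samples, proteins))
  provenance <- list()
  for (prot in proteins) {
    sub <- values[values$protein == prot, , drop = FALSE]
    peps <- unique(sub$peptide)
    w <- if (weights == "equal" || length(peps) == 1) {
      stats::setNames(rep(1, length(peps)), peps)
    } else {
      v <- vapply(peps, function(p) {
        x <- sub$value[sub$peptide == p]
        x <- x[!is.na(x)]
        if (length(x) < 2) NA_real_ else stats::var(x)
      }, numeric(1))
      if (all(is.na(v))) v[] <- 1
      v[is.na(v)] <- max(v, na.rm = TRUE)
      v <- pmax(v, 1e-12)
      stats::setNames(1 / v, peps)
    }
    w <- w / sum(w)
    provenance[[prot]] <- data.frame(peptide = names(w), weight = unname(w),
                                     stringsAsFactors = FALSE)
    wide <- matrix(NA_real_, length(samples), length(peps),
                   dimnames = list(samples, peps))
    idx <- cbind(match(sub$sample_id, samples), match(sub$peptide, peps))
    wide[idx] <- sub$value
    for (i in seq_along(samples)) {
      present <- !is.na(wide[i, ])
      if (!any(present)) next
      wi <- w[present] / sum(w[present])
      mat[i, prot] <- sum(wi * wide[i, present])
    }
  }
  protein_matrix(mat, provenance = provenance)
}
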