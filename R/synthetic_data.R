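# Synthetic-data generators for the three experiment classes of a targeted
# SRM/MRM study: calibration dilution series with blanks, a multi-day
# replicate design, and a three-class clinical cohort. Every generator takes
# an explicit seed and restores the caller's RNG state.

.with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Mean-one lognormal multiplier with coefficient of variation cv.
.lognorm_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sigma^2 / 2, sigma))
}

.default_proteins <- c("GNMT", "AHCY", "CBS", "CGL", "DHFR", "MAT1A", "MAT2A",
                       "MAT2B", "MTAP", "BHMT", "SHMT1", "SHMT2", "METH")

#' Default 13-protein / 40-peptide monitored panel
#'
#' A synthetic stand-in panel covering the 13 one-carbon metabolism enzymes
#' monitored by the assay (GNMT, AHCY, CBS, CGL, DHFR, MAT1A, MAT2A, MAT2B,
#' MTAP, BHMT, SHMT1, SHMT2, METH), with 40 surrogate tryptic peptides
#' (three per protein, four for GNMT) and three fragment-ion transitions per
#' peptide. Peptide sequences are generated deterministically and are
#' synthetic: they are plausible tryptic products, not the assay's real
#' sequences.
#'
#' @return Data frame with columns `protein`, `peptide`, `fragment`,
#'   `frag_fraction` (the share of the peptide signal carried by each
#'   transition; sums to 1 within a peptide).
#' @export
default_panel <- function() {
  .with_seed(104729L, {
    n_pep <- c(4L, rep(3L, 12L))
    residues <- setdiff(strsplit("ACDEFGHIKLNPQSTVY", "")[[1]], c("K", "R"))
    rows <- list()
    for (i in seq_along(.default_proteins)) {
      for (j in seq_len(n_pep[i])) {
        len <- sample(8:16, 1)
        body <- paste(sample(residues, len - 1, replace = TRUE), collapse = "")
        pep <- paste0(body, sample(c("K", "R"), 1))
        fr <- stats::runif(3, 0.5, 1.5)
        fr <- fr / sum(fr)
        rows[[length(rows) + 1L]] <- data.frame(
          protein = .default_proteins[i],
          peptide = pep,
          fragment = c("y4", "y5", "y6"),
          frag_fraction = fr,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
}

#' Ground truth for the synthetic generators
#'
#' Bundles every simulated quantity: per-peptide calibration response slopes
#' (area units per fmol), blank background signal (mean and SD in area
#' units), a concentration-to-CV map describing how multiplicative
#' measurement noise inflates toward the detection limit, intra-/inter-assay
#' variance components for the replicate design, and per-protein clinical
#' condition effects (log2 fold changes vs control).
#'
#' @param panel Panel data frame as from [default_panel()].
#' @param slope Named numeric vector (by peptide) of response slopes, > 0.
#' @param background_mean,background_sd Named numeric vectors (by peptide) of
#'   blank signal mean and SD in area units, >= 0.
#' @param cv_at_level Named numeric vector mapping spike level (fmol, as
#'   names) to multiplicative CV (fraction). Intermediate levels are
#'   interpolated on the log10 concentration scale.
#' @param intra_cv,inter_cv Within-day and between-day variance components of
#'   the replicate design, as fractions on the natural-log area scale.
#' @param effects Data frame `protein`, `cirrhosis`, `hcc`: log2 fold change
#'   of each protein vs control in each disease class.
#' @param baseline Named numeric vector (by protein) of control-group log2
#'   abundance baselines.
#' @param peptide_offset Named numeric vector (by peptide) of fixed log2
#'   response offsets (ionization efficiency differences).
#' @param noise_sd Residual biological + technical SD of clinical log2
#'   peptide abundances.
#' @param subject_sd SD of a per-sample offset shared by all peptides of a
#'   subject (global biological level differences).
#' @param tech_sd SD of per-run technical log2 factors applied to both the
#'   endogenous signal and the heavy standard; removed by normalization.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(panel, slope, background_mean, background_sd,
                         cv_at_level, intra_cv, inter_cv,
                         effects, baseline, peptide_offset,
                         noise_sd = 0.5, subject_sd = 0.2, tech_sd = 0.15) {
  peptides <- unique(panel$peptide)
  pep_prot <- unique(panel[c("peptide", "protein")])
  if (anyDuplicated(pep_prot$peptide)) {
    stop("every peptide must map to exactly one protein", call. = FALSE)
  }
  if (any(slope[peptides] <= 0) || anyNA(slope[peptides])) {
    stop("slopes must be positive for every panel peptide", call. = FALSE)
  }
  if (any(cv_at_level < 0) || intra_cv < 0 || inter_cv < 0) {
    stop("CVs must be nonnegative", call. = FALSE)
  }
  structure(list(
    panel = panel, slope = slope,
    background_mean = background_mean, background_sd = background_sd,
    cv_at_level = cv_at_level, intra_cv = intra_cv, inter_cv = inter_cv,
    effects = effects, baseline = baseline, peptide_offset = peptide_offset,
    noise_sd = noise_sd, subject_sd = subject_sd, tech_sd = tech_sd
  ), class = "ground_truth")
}

#' Default ground truth emulating the study conditions
#'
#' Calibration response slopes span roughly 1000-4000 area units/fmol;
#' background levels are set per peptide so that blank-derived detection
#' limits fall in the low-fmol range; measurement CV inflates from ~4% at
#' high load to ~30% at 0.5 fmol; replicate-design variance components are
#' 5% within-day and 8% between-day; and clinical effects place one protein
#' cluster (GNMT, CBS, CGL, MAT1A, BHMT, SHMT1, SHMT2) down in disease and
#' the other (AHCY, DHFR, MAT2A, MAT2B, MTAP, METH) up, with cirrhosis
#' intermediate between control and HCC.
#'
#' @param panel Panel data frame; defaults to [default_panel()].
#' @param hcc_effect Absolute log2 fold change of HCC vs control per protein.
#' @param cirrhosis_fraction Cirrhosis effect as a fraction of the HCC
#'   effect (0.5 = halfway between control and HCC).
#' @param noise_sd Clinical residual SD on the log2 scale.
#' @return A `ground_truth`.
#' @export
default_ground_truth <- function(panel = default_panel(), hcc_effect = 1.2,
                                 cirrhosis_fraction = 0.5, noise_sd = 0.5) {
  peptides <- unique(panel$peptide)
  proteins <- unique(panel$protein)
  .with_seed(7919L, {
    slope <- stats::setNames(exp(stats::runif(length(peptides),
                                              log(1000), log(4000))), peptides)
    llod_target <- stats::setNames(stats::runif(length(peptides), 0.8, 5),
                                   peptides)
    bg_mean <- slope * llod_target * 0.4
    bg_sd <- slope * llod_target * 0.2
    baseline <- stats::setNames(stats::rnorm(length(proteins), 4, 1), proteins)
    pep_offset <- stats::setNames(stats::rnorm(length(peptides), 0, 0.3),
                                  peptides)
    cluster1 <- c("GNMT", "CBS", "CGL", "MAT1A", "BHMT", "SHMT1", "SHMT2")
    sign_vec <- ifelse(proteins %in% cluster1, -1, 1)
    effects <- data.frame(
      protein = proteins,
      cirrhosis = sign_vec * hcc_effect * cirrhosis_fraction,
      hcc = sign_vec * hcc_effect,
      stringsAsFactors = FALSE
    )
    ground_truth(
      panel = panel, slope = slope,
      background_mean = bg_mean, background_sd = bg_sd,
      cv_at_level = c("0.5" = 0.30, "1" = 0.16, "4" = 0.08, "10" = 0.06,
                      "50" = 0.05, "100" = 0.04, "500" = 0.04, "1000" = 0.04),
      intra_cv = 0.05, inter_cv = 0.08,
      effects = effects, baseline = baseline, peptide_offset = pep_offset,
      noise_sd = noise_sd
    )
  })
}

#' Interpolate the truth's CV at an arbitrary spike level
#' @param truth A `ground_truth`.
#' @param level Spike level in fmol.
#' @return CV fraction at that level.
#' @export
cv_at <- function(truth, level) {
  map <- truth$cv_at_level
  xs <- log10(as.numeric(names(map)))
  if (length(map) == 1) return(unname(map[1]))
  stats::approx(xs, as.numeric(map), xout = log10(level), rule = 2)$y
}

#' Clinical cohort design
#'
#' @param n_control,n_cirrhosis,n_hcc Sample counts per class (default
#'   28/15/19, the cohort sizes the generators emulate).
#' @param cluster1,cluster2 Disjoint protein sets with opposite regulation
#'   across disease classes.
#' @return Object of class `cohort_design`.
#' @export
cohort_design <- function(n_control = 28, n_cirrhosis = 15, n_hcc = 19,
                          cluster1 = c("GNMT", "CBS", "CGL", "MAT1A",
                                       "BHMT", "SHMT1", "SHMT2"),
                          cluster2 = c("AHCY", "DHFR", "MAT2A", "MAT2B",
                                       "MTAP", "METH")) {
  if (min(n_control, n_cirrhosis, n_hcc) < 2) {
    stop("each class needs at least 2 samples", call. = FALSE)
  }
  if (length(intersect(cluster1, cluster2)) > 0) {
    stop("cluster1 and cluster2 must be disjoint", call. = FALSE)
  }
  structure(list(n_control = n_control, n_cirrhosis = n_cirrhosis,
                 n_hcc = n_hcc, cluster1 = cluster1, cluster2 = cluster2),
            class = "cohort_design")
}

.background_draw <- function(n, mean, sd) {
  pmax(0, stats::rnorm(n, mean, sd))
}

#' Generate a calibration dilution series with blank runs
#'
#' Heavy (stable-isotope-labeled) peptides are spiked over a dilution series
#' (default 0.5-1000 fmol) into a background matrix together with a fixed
#' amount of the light counterpart (default 100 fmol). Heavy areas follow
#' `slope * level` scaled by a mean-one lognormal with the level-dependent
#' CV, plus additive truncated-Gaussian background; blanks carry background
#' only.
#'
#' @param truth A `ground_truth`.
#' @param levels Sorted positive spike levels in fmol.
#' @param n_blanks Number of blank matrix runs (>= 3).
#' @param n_replicates Injection replicates per level.
#' @param counterpart_fmol Fixed spike of the light counterpart.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return List with `transitions` (transition table) and `metadata`.
#' @export
generate_calibration <- function(truth, levels = c(0.5, 1, 4, 10, 50, 100,
                                                   500, 1000),
                                 n_blanks = 3, n_replicates = 3,
                                 counterpart_fmol = 100, seed) {
  if (any(levels <= 0)) stop("levels must be positive", call. = FALSE)
  if (is.unsorted(levels, strictly = TRUE)) {
    stop("levels must be sorted increasing", call. = FALSE)
  }
  if (n_blanks < 3) stop("at least 3 blank runs are required", call. = FALSE)
  panel <- truth$panel
  .with_seed(seed, {
    rows <- vector("list", 0)
    meta <- vector("list", 0)
    emit <- function(run_id, spike, run_type, rep_idx) {
      n <- nrow(panel)
      cv_h <- if (spike > 0) cv_at(truth, spike) else 0
      cv_l <- if (counterpart_fmol > 0) cv_at(truth, counterpart_fmol) else 0
      sl <- truth$slope[panel$peptide] * panel$frag_fraction
      bgm <- truth$background_mean[panel$peptide] * panel$frag_fraction
      bgs <- truth$background_sd[panel$peptide] * sqrt(panel$frag_fraction)
      heavy <- if (run_type == "blank") {
        .background_draw(n, bgm, bgs)
      } else {
        sl * spike * .lognorm_factor(n, cv_h) + .background_draw(n, bgm, bgs)
      }
      light <- if (run_type == "blank") {
        .background_draw(n, bgm, bgs)
      } else {
        sl * counterpart_fmol * .lognorm_factor(n, cv_l) +
          .background_draw(n, bgm, bgs)
      }
      rows[[length(rows) + 1L]] <<- data.frame(
        run_id = run_id, protein = rep(panel$protein, 2),
        peptide = rep(panel$peptide, 2),
        precursor_charge = 2L, fragment = rep(panel$fragment, 2),
        label = rep(c("heavy", "light"), each = n),
        rt_min = 30, area = c(heavy, light), stringsAsFactors = FALSE
      )
      meta[[length(meta) + 1L]] <<- data.frame(
        run_id = run_id, run_type = run_type,
        spike_fmol = spike, counterpart_fmol = counterpart_fmol,
        replicate_index = rep_idx, day_index = NA_integer_,
        sample_id = NA_character_, condition = NA_character_,
        stringsAsFactors = FALSE
      )
    }
    for (b in seq_len(n_blanks)) {
      emit(sprintf("blank_%02d", b), 0, "blank", b)
    }
    for (lv in levels) {
      for (r in seq_len(n_replicates)) {
        emit(sprintf("cal_%g_r%d", lv, r), lv, "calibration", r)
      }
    }
    list(transitions = do.call(rbind, rows), metadata = do.call(rbind, meta))
  })
}

#' Generate a multi-day replicate design
#'
#' Heavy peptides at a few fixed levels (default 5/50/500 fmol) measured in
#' triplicate on each of several days, with the light counterpart at a fixed
#' 30 fmol. Heavy areas are `expected * exp(day_effect) * exp(rep_noise)`
#' with `day_effect ~ N(0, inter_cv)` shared within a day and
#' `rep_noise ~ N(0, intra_cv)` per injection, both on the log scale.
#'
#' @param truth A `ground_truth`.
#' @param levels Spike levels in fmol.
#' @param light_fmol Fixed light spike.
#' @param days Number of days (>= 2).
#' @param reps_per_day Injections per day (>= 2).
#' @param seed Integer seed.
#' @return List with `transitions` and `metadata`.
#' @export
generate_replicate_design <- function(truth, levels = c(5, 50, 500),
                                      light_fmol = 30, days = 5,
                                      reps_per_day = 3, seed) {
  if (days < 2 || reps_per_day < 2) {
    stop("need at least 2 days and 2 replicates per day", call. = FALSE)
  }
  if (any(levels <= 0)) stop("levels must be positive", call. = FALSE)
  panel <- truth$panel
  .with_seed(seed, {
    rows <- vector("list", 0)
    meta <- vector("list", 0)
    n <- nrow(panel)
    sl <- truth$slope[panel$peptide] * panel$frag_fraction
    for (lv in levels) {
      for (d in seq_len(days)) {
        day_eff <- stats::rnorm(n, 0, truth$inter_cv)
        for (r in seq_len(reps_per_day)) {
          rep_noise <- stats::rnorm(n, 0, truth$intra_cv)
          run_id <- sprintf("rep_%g_d%d_r%d", lv, d, r)
          heavy <- sl * lv * exp(day_eff + rep_noise)
          light <- sl * light_fmol
          rows[[length(rows) + 1L]] <- data.frame(
            run_id = run_id, protein = rep(panel$protein, 2),
            peptide = rep(panel$peptide, 2), precursor_charge = 2L,
            fragment = rep(panel$fragment, 2),
            label = rep(c("heavy", "light"), each = n),
            rt_min = 30, area = c(heavy, light), stringsAsFactors = FALSE
          )
          meta[[length(meta) + 1L]] <- data.frame(
            run_id = run_id, run_type = "replicate_design",
            spike_fmol = lv, counterpart_fmol = light_fmol,
            replicate_index = r, day_index = d,
            sample_id = NA_character_, condition = NA_character_,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    list(transitions = do.call(rbind, rows), metadata = do.call(rbind, meta))
  })
}

#' Generate a clinical cohort at the peptide level
#'
#' Simulates log2 peptide abundances for a control/cirrhosis/HCC cohort.
#' Each value is `protein baseline + condition effect + peptide offset +
#' subject offset + run technical factor + Gaussian noise`; heavy-standard
#' areas for each run share the technical factor so that downstream
#' normalization can remove it. Effects in cirrhosis are configured
#' intermediate between control and HCC by default.
#'
#' @param design A `cohort_design`.
#' @param truth A `ground_truth`; its `effects` table must cover every
#'   protein in the design clusters.
#' @param seed Integer seed.
#' @return List with `peptides` (data frame `sample_id`, `protein`,
#'   `peptide`, `log2_light`, `heavy_area`), `metadata`, and `labels`
#'   (named condition factor).
#' @export
generate_cohort <- function(design, truth, seed) {
  proteins <- unique(truth$panel$protein)
  unknown <- setdiff(c(design$cluster1, design$cluster2), proteins)
  if (length(unknown) > 0) {
    stop("unknown protein(s) in cohort clusters: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  conditions <- c(rep("control", design$n_control),
                  rep("cirrhosis", design$n_cirrhosis),
                  rep("HCC", design$n_hcc))
  n_samp <- length(conditions)
  sample_ids <- sprintf("S%03d", seq_len(n_samp))
  eff <- truth$effects
  rownames(eff) <- eff$protein
  pep_prot <- unique(truth$panel[c("peptide", "protein")])
  .with_seed(seed, {
    subj_eff <- stats::rnorm(n_samp, 0, truth$subject_sd)
    tech <- stats::rnorm(n_samp, 0, truth$tech_sd)
    rows <- vector("list", n_samp)
    for (i in seq_len(n_samp)) {
      cond_shift <- switch(conditions[i],
        control = rep(0, nrow(pep_prot)),
        cirrhosis = eff[pep_prot$protein, "cirrhosis"],
        HCC = eff[pep_prot$protein, "hcc"]
      )
      mu <- truth$baseline[pep_prot$protein] + cond_shift +
        truth$peptide_offset[pep_prot$peptide] + subj_eff[i] + tech[i]
      log2_light <- mu + stats::rnorm(nrow(pep_prot), 0, truth$noise_sd)
      heavy_area <- truth$slope[pep_prot$peptide] * 100 *
        2^(tech[i] + stats::rnorm(nrow(pep_prot), 0, 0.05))
      rows[[i]] <- data.frame(
        sample_id = sample_ids[i], protein = pep_prot$protein,
        peptide = pep_prot$peptide, log2_light = log2_light,
        heavy_area = heavy_area, stringsAsFactors = FALSE
      )
    }
    metadata <- data.frame(
      run_id = sample_ids, run_type = "clinical",
      spike_fmol = NA_real_, counterpart_fmol = 100,
      replicate_index = NA_integer_, day_index = NA_integer_,
      sample_id = sample_ids, condition = conditions,
      stringsAsFactors = FALSE
    )
    list(peptides = do.call(rbind, rows), metadata = metadata,
         labels = stats::setNames(factor(conditions, levels = .conditions),
                                  sample_ids))
  })
}
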