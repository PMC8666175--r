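# End-to-end orchestration: simulate -> qc -> quantify -> diff -> classify,
# with every stage writing its report and a parameter log. Deterministic
# given (config, seed): stage seeds are fixed offsets from the master seed.

#' Build a pipeline configuration
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master integer seed; every random draw derives from it.
#' @param levels Calibration dilution levels in fmol.
#' @param n_blanks Blank matrix runs in the calibration experiment.
#' @param replicate_levels Replicate-design spike levels in fmol.
#' @param days,reps_per_day Replicate-design grid.
#' @param cv_threshold Peptide acceptance CV threshold in percent.
#' @param fold_tolerance Interference screening fold tolerance.
#' @param fdr_level Significance level on q-values.
#' @param max_panel Largest classifier panel size.
#' @param algorithms Classifier set for the accuracy grid.
#' @param final_algorithm,final_panel_size Model reported in full.
#' @param rank_once Rank proteins once on all data instead of per fold.
#' @param rollup_weights `"inverse_variance"` or `"equal"`.
#' @param truth,design Ground truth and cohort design for simulation;
#'   defaults emulate the study conditions.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("mrmquant_"), seed = 1,
                            levels = c(0.5, 1, 4, 10, 50, 100, 500, 1000),
                            n_blanks = 3, replicate_levels = c(5, 50, 500),
                            days = 5, reps_per_day = 3,
                            cv_threshold = 20, fold_tolerance = 2,
                            fdr_level = 0.05, max_panel = 13,
                            algorithms = c("lda", "qda", "multinomial",
                                           "random_forest"),
                            final_algorithm = "qda", final_panel_size = 6,
                            rank_once = FALSE,
                            rollup_weights = "inverse_variance",
                            truth = NULL, design = NULL) {
  if (cv_threshold < 0 || fold_tolerance <= 1 || fdr_level <= 0) {
    stop("thresholds must be positive (fold_tolerance > 1)", call. = FALSE)
  }
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), levels = levels,
    n_blanks = n_blanks, replicate_levels = replicate_levels, days = days,
    reps_per_day = reps_per_day, cv_threshold = cv_threshold,
    fold_tolerance = fold_tolerance, fdr_level = fdr_level,
    max_panel = max_panel, algorithms = algorithms,
    final_algorithm = final_algorithm, final_panel_size = final_panel_size,
    rank_once = rank_once, rollup_weights = rollup_weights,
    truth = if (is.null(truth)) default_ground_truth() else truth,
    design = if (is.null(design)) cohort_design() else design
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields of the YAML override the defaults of [pipeline_config()];
#' fields not present keep their defaults.
#'
#' @param path YAML file.
#' @param ... Further overrides applied after the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(pipeline_config)), c("truth", "design"))
  cfg <- cfg[intersect(names(cfg), allowed)]
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  do.call(pipeline_config, cfg)
}

.log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...))
  writeLines(msg, con)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Simulates the three experiment classes (calibration dilution series,
#' multi-day replicate design, clinical cohort), characterizes the assay,
#' quantifies and normalizes the cohort, rolls peptides up to proteins,
#' tests condition effects with FDR control, runs PCA and Ward clustering,
#' evaluates nested biomarker panels under LOOCV, and writes every stage
#' report plus a parameter log under `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline_log.txt")
  con <- file(log_path, open = "wt")
  on.exit(close(con))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .log_line(con, "stage %s FAILED: %s", name, conditionMessage(e))
      writeLines("incomplete", file.path(config$out_dir, "INCOMPLETE"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  .log_line(con, "mrmquant %s | master seed %d",
            as.character(utils::packageVersion("mrmquant")), config$seed)

  # -- simulate ---------------------------------------------------------------
  truth <- config$truth
  sim <- stage("simulate", {
    cal <- generate_calibration(truth, levels = config$levels,
                                n_blanks = config$n_blanks,
                                seed = config$seed + 101L)
    rep_des <- generate_replicate_design(truth,
                                         levels = config$replicate_levels,
                                         days = config$days,
                                         reps_per_day = config$reps_per_day,
                                         seed = config$seed + 202L)
    coh <- generate_cohort(config$design, truth, seed = config$seed + 303L)
    write_transition_report(cal$transitions,
                            file.path(config$out_dir, "calibration.csv"))
    write_run_metadata(cal$metadata,
                       file.path(config$out_dir, "calibration_meta.csv"))
    write_transition_report(rep_des$transitions,
                            file.path(config$out_dir, "replicate.csv"))
    write_run_metadata(rep_des$metadata,
                       file.path(config$out_dir, "replicate_meta.csv"))
    write_run_metadata(coh$metadata,
                       file.path(config$out_dir, "cohort_meta.csv"))
    .write_table(coh$peptides, file.path(config$out_dir, "cohort_peptides.csv"),
                 c("log2_light", "heavy_area"))
    list(cal = cal, rep_des = rep_des, coh = coh)
  })
  .log_line(con, "simulate: %d calibration rows, %d replicate rows, %d cohort rows",
            nrow(sim$cal$transitions), nrow(sim$rep_des$transitions),
            nrow(sim$coh$peptides))

  # -- qc ---------------------------------------------------------------------
  qc <- stage("qc", {
    rep <- build_assay_report(sim$cal, sim$rep_des,
                              cv_threshold = config$cv_threshold,
                              fold_tolerance = config$fold_tolerance)
    write_assay_report(rep,
                       file.path(config$out_dir, "assay_report_peptides.csv"),
                       file.path(config$out_dir, "assay_report_proteins.csv"))
    rep
  })
  n_acc <- sum(qc$peptides$accepted)
  .log_line(con, "qc: %d/%d peptides accepted (CV < %g%%)",
            n_acc, nrow(qc$peptides), config$cv_threshold)
  if (n_acc == 0) {
    .log_line(con, "qc: WARNING no peptide passed the CV filter; %s",
              "downstream stages use the full panel")
  }

  # -- quantify ---------------------------------------------------------------
  quant <- stage("quantify", {
    pep <- sim$coh$peptides
    norm <- normalize_runs(
      data.frame(sample_id = pep$sample_id, peptide = pep$peptide,
                 protein = pep$protein, value = pep$log2_light,
                 stringsAsFactors = FALSE),
      data.frame(sample_id = pep$sample_id, peptide = pep$peptide,
                 heavy_area = pep$heavy_area, stringsAsFactors = FALSE))
    mat <- rollup(norm$values, weights = config$rollup_weights)
    write_protein_matrix(mat, file.path(config$out_dir, "protein_matrix.csv"))
    .write_table(norm$factors,
                 file.path(config$out_dir, "normalization_factors.csv"),
                 "factor_log2")
    list(matrix = mat, factors = norm$factors)
  })
  .log_line(con, "quantify: %d samples x %d proteins",
            nrow(quant$matrix), ncol(quant$matrix))

  # -- diff -------------------------------------------------------------------
  diff_res <- stage("diff", {
    res <- fit_condition_model(quant$matrix, sim$coh$metadata)
    .write_table(res, file.path(config$out_dir, "differential.csv"),
                 c("effect", "statistic", "p_value", "q_value"))
    res
  })
  sig <- diff_res[diff_res$contrast != "omnibus" &
                    !is.na(diff_res$q_value) &
                    diff_res$q_value < config$fdr_level, ]
  .log_line(con, "diff: %d significant protein-contrast calls at q < %g",
            nrow(sig), config$fdr_level)

  multivar <- stage("multivariate", {
    complete <- impute_halfmin(quant$matrix)
    pca <- run_pca(complete)
    clust <- cluster_proteins(complete, k = 2)
    .write_table(data.frame(sample_id = rownames(pca$scores), pca$scores,
                            stringsAsFactors = FALSE),
                 file.path(config$out_dir, "pca_scores.csv"),
                 colnames(pca$scores))
    writeLines(clust$newick, file.path(config$out_dir, "protein_dendrogram.nwk"))
    list(pca = pca, clusters = clust, complete = complete)
  })
  .log_line(con, "multivariate: PC1 explains %.1f%% of variance",
            100 * multivar$pca$var_explained[1])

  # -- classify ---------------------------------------------------------------
  cls <- stage("classify", {
    labels <- sim$coh$labels[rownames(multivar$complete)]
    grid <- evaluate_panels(multivar$complete, labels,
                            algorithms = config$algorithms,
                            max_panel = config$max_panel,
                            seed = config$seed + 404L,
                            rank_once = config$rank_once)
    panel <- grid$ranking$protein[seq_len(min(config$final_panel_size,
                                              nrow(grid$ranking)))]
    report <- final_model_report(multivar$complete, labels, panel,
                                 algorithm = config$final_algorithm,
                                 seed = config$seed + 505L)
    acc_df <- data.frame(panel_size = as.integer(rownames(grid$accuracy)),
                         grid$accuracy, check.names = FALSE)
    .write_table(acc_df, file.path(config$out_dir, "accuracy_grid.csv"),
                 colnames(grid$accuracy))
    write_classification_report(report,
                                file.path(config$out_dir,
                                          "classification_report.json"))
    list(grid = grid, report = report)
  })
  .log_line(con, "classify: %s %d-protein panel, LOOCV accuracy %.2f%%",
            config$final_algorithm, length(cls$report$selected_panel),
            cls$report$out_of_sample_accuracy)
  .log_line(con, "pipeline complete")
  invisible(list(config = config, simulate = sim, qc = qc, quantify = quant,
                 differential = diff_res, multivariate = multivar,
                 classification = cls))
}
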