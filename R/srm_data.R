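# Readers and writers for transition-level SRM reports, run metadata,
# protein abundance matrices and result reports. All tables are long/tidy
# data frames with fixed column names; numeric round-trips are lossless.

#' Column names of a transition report
#'
#' A transition report holds one chromatographic peak area per
#' (run, peptide, precursor charge, fragment ion, label) combination,
#' matching the layout of a Skyline-style custom report export.
#'
#' @format Character vector of required column names.
#' @export
transition_columns <- c(
  "run_id", "protein", "peptide", "precursor_charge",
  "fragment", "label", "rt_min", "area"
)

#' Column names of a run metadata table
#' @format Character vector of required column names.
#' @export
metadata_columns <- c(
  "run_id", "run_type", "spike_fmol", "counterpart_fmol",
  "replicate_index", "day_index", "sample_id", "condition"
)

.aa_regex <- "^[ACDEFGHIKLMNPQRSTVWY]+$"
.run_types <- c("blank", "calibration", "replicate_design", "clinical")
.conditions <- c("control", "cirrhosis", "HCC")

# Full-precision numeric serialization: 17 significant digits round-trip
# IEEE doubles exactly through decimal text.
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

.write_table <- function(df, path, numeric_cols) {
  out <- df
  for (col in intersect(numeric_cols, names(out))) {
    out[[col]] <- .fmt_num(as.numeric(out[[col]]))
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("cannot write to '", path, "': ", conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

#' Read a transition-level peak area report
#'
#' Parses a long-format CSV with one peak area per row (columns
#' [transition_columns]). Empty `area` fields are preserved as `NA`,
#' never coerced to zero: a zero is a legal measured blank signal while
#' `NA` means no integration was possible.
#'
#' @param path Path to a CSV file with a header row.
#' @param strict If `TRUE` (default) any invalid row aborts with an error
#'   citing the offending file line. If `FALSE` invalid rows are dropped and
#'   returned in the `"rejected"` attribute (a data frame of `line`,
#'   `reason`), so that `nrow(parsed) + nrow(rejected)` equals the number of
#'   data lines read.
#' @return A data frame of validated transition measurements.
#' @export
read_transition_report <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = "character")
  missing_cols <- setdiff(transition_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("malformed transition report header; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[transition_columns]
  df$precursor_charge <- suppressWarnings(as.integer(df$precursor_charge))
  df$rt_min <- suppressWarnings(as.numeric(df$rt_min))
  df$area <- suppressWarnings(as.numeric(df$area))
  validate_transition_table(df, strict = strict, line_offset = 1L)
}

#' Validate a transition table
#'
#' Enforces the invariants of a transition report: peptides are uppercase
#' amino-acid strings, labels are `light`/`heavy`, areas are missing or
#' nonnegative, retention times nonnegative, and the
#' (run, peptide, charge, fragment, label) key is unique.
#'
#' @param df Data frame with [transition_columns].
#' @param strict Abort on first invalid row (`TRUE`) or collect rejects.
#' @param line_offset Added to row indices when reporting file lines
#'   (1 for a CSV with a header row).
#' @return The validated data frame (with a `"rejected"` attribute when
#'   `strict = FALSE`).
#' @export
validate_transition_table <- function(df, strict = TRUE, line_offset = 0L) {
  reasons <- rep(NA_character_, nrow(df))
  bad <- function(idx, why) {
    sel <- idx & is.na(reasons)
    reasons[sel] <<- why
  }
  bad(!grepl(.aa_regex, df$peptide), "invalid peptide sequence")
  bad(!(df$label %in% c("light", "heavy")), "label must be 'light' or 'heavy'")
  bad(is.na(df$precursor_charge) | df$precursor_charge < 1L,
      "precursor_charge must be a positive integer")
  bad(!is.na(df$area) & df$area < 0, "negative peak area")
  bad(!is.na(df$rt_min) & df$rt_min < 0, "negative retention time")
  key <- do.call(paste, c(df[c("run_id", "peptide", "precursor_charge",
                               "fragment", "label")], sep = "\r"))
  bad(duplicated(key) | duplicated(key, fromLast = TRUE),
      "duplicate (run, peptide, charge, fragment, label) key")
  invalid <- which(!is.na(reasons))
  if (length(invalid) > 0 && strict) {
    i <- invalid[1]
    stop("invalid transition row at line ", i + line_offset, ": ",
         reasons[i], call. = FALSE)
  }
  rejected <- data.frame(line = invalid + line_offset,
                         reason = reasons[invalid],
                         stringsAsFactors = FALSE)
  out <- df[setdiff(seq_len(nrow(df)), invalid), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write a transition report to CSV at full numeric precision
#' @param df Transition table.
#' @param path Output CSV path.
#' @export
write_transition_report <- function(df, path) {
  .write_table(df[transition_columns], path, c("rt_min", "area"))
}

#' Read a run metadata table
#'
#' @param path CSV with columns [metadata_columns]. Fields that do not apply
#'   to a run type (e.g. `condition` for a calibration run) are empty.
#' @return Validated data frame of run metadata.
#' @export
read_run_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = "character")
  missing_cols <- setdiff(metadata_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("malformed metadata header; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[metadata_columns]
  for (col in c("spike_fmol", "counterpart_fmol")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  for (col in c("replicate_index", "day_index")) {
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  }
  validate_run_metadata(df)
}

#' Validate run metadata invariants
#' @param df Metadata data frame.
#' @return The data frame, invisibly validated.
#' @export
validate_run_metadata <- function(df) {
  if (anyDuplicated(df$run_id)) {
    stop("duplicate run_id in metadata", call. = FALSE)
  }
  if (!all(df$run_type %in% .run_types)) {
    stop("run_type must be one of: ", paste(.run_types, collapse = ", "),
         call. = FALSE)
  }
  blanks <- df$run_type == "blank"
  if (any(blanks & !is.na(df$spike_fmol) & df$spike_fmol != 0)) {
    stop("blank runs must have spike_fmol = 0", call. = FALSE)
  }
  clin <- df$run_type == "clinical"
  if (any(clin & (is.na(df$condition) | !(df$condition %in% .conditions)))) {
    stop("clinical runs require exactly one condition in {",
         paste(.conditions, collapse = ", "), "}", call. = FALSE)
  }
  df
}

#' Write run metadata to CSV
#' @param df Metadata table.
#' @param path Output CSV path.
#' @export
write_run_metadata <- function(df, path) {
  .write_table(df[metadata_columns], path, c("spike_fmol", "counterpart_fmol"))
}

# ---- protein abundance matrix ----------------------------------------------

#' Construct a protein abundance matrix
#'
#' Samples-by-proteins matrix of normalized log2 abundance estimators, with
#' optional provenance (per-protein contributing peptides and rollup weights).
#'
#' @param values Numeric matrix, rows = samples, columns = proteins; dimnames
#'   required and unique. `NA` cells are allowed.
#' @param provenance Optional named list (by protein) of data frames with
#'   columns `peptide`, `weight`.
#' @return An object of class `protein_matrix` (a matrix with attributes).
#' @export
protein_matrix <- function(values, provenance = NULL) {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("protein matrix requires sample and protein dimnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("sample and protein labels must be unique", call. = FALSE)
  }
  structure(values, provenance = provenance, class = c("protein_matrix", "matrix"))
}

#' Write a protein abundance matrix to CSV (samples as rows)
#' @param mat `protein_matrix` or plain matrix with dimnames.
#' @param path Output CSV path.
#' @export
write_protein_matrix <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat),
                   as.data.frame(unclass(mat)[, , drop = FALSE]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_table(df, path, colnames(mat))
}

#' Read a protein abundance matrix from CSV
#' @param path CSV written by [write_protein_matrix()].
#' @return A `protein_matrix`.
#' @export
read_protein_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$sample_id
  protein_matrix(m)
}

# ---- assay report -----------------------------------------------------------

#' Assemble an assay report object
#'
#' @param peptides Data frame of per-peptide figures of merit (LLOD, LLOQ,
#'   R-squared, CV components per spike level, acceptance flag).
#' @param proteins Data frame of per-protein figures of merit.
#' @return Object of class `assay_report`.
#' @export
assay_report <- function(peptides, proteins) {
  structure(list(peptides = peptides, proteins = proteins),
            class = "assay_report")
}

#' Write an assay report (two CSV tables) at full precision
#' @param report `assay_report`.
#' @param peptide_path CSV path for the per-peptide table.
#' @param protein_path CSV path for the per-protein table (optional).
#' @export
write_assay_report <- function(report, peptide_path, protein_path = NULL) {
  num_cols <- function(df) names(df)[vapply(df, is.numeric, logical(1))]
  .write_table(report$peptides, peptide_path, num_cols(report$peptides))
  if (!is.null(protein_path)) {
    .write_table(report$proteins, protein_path, num_cols(report$proteins))
  }
  invisible(report)
}

#' Read an assay report written by [write_assay_report()]
#' @param peptide_path Per-peptide CSV.
#' @param protein_path Per-protein CSV (optional).
#' @return An `assay_report`.
#' @export
read_assay_report <- function(peptide_path, protein_path = NULL) {
  pep <- utils::read.csv(peptide_path, stringsAsFactors = FALSE, na.strings = "")
  prot <- if (!is.null(protein_path)) {
    utils::read.csv(protein_path, stringsAsFactors = FALSE, na.strings = "")
  } else {
    data.frame()
  }
  assay_report(pep, prot)
}

# ---- classification report --------------------------------------------------

#' Write a classification report as JSON
#'
#' The confusion matrix is serialized as nested integer lists (true class by
#' predicted class); all numeric fields keep full precision.
#'
#' @param report `classification_report` from [final_model_report()].
#' @param path Output JSON path.
#' @export
write_classification_report <- function(report, path) {
  obj <- list(
    algorithm = report$algorithm,
    selected_panel = report$selected_panel,
    in_sample_accuracy = report$in_sample_accuracy,
    out_of_sample_accuracy = report$out_of_sample_accuracy,
    classes = rownames(report$confusion),
    confusion = unname(apply(report$confusion, 1, as.integer, simplify = FALSE)),
    auc = as.list(report$auc)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a classification report written by [write_classification_report()]
#' @param path JSON path.
#' @return A list with the report fields; `confusion` is an integer matrix.
#' @export
read_classification_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  conf <- obj$confusion
  if (is.list(conf)) conf <- do.call(rbind, conf)
  conf <- matrix(as.integer(conf), nrow = length(obj$classes),
                 dimnames = list(true = obj$classes, predicted = obj$classes))
  obj$confusion <- conf
  obj$auc <- unlist(obj$auc)
  obj
}
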