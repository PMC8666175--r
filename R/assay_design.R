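# In-silico tryptic digestion and proteotypic candidate selection for
# building an SRM/MRM method.

#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence after lysine (K) or arginine (R) except when
#' the next residue is proline (the standard KP/RP exception), and
#' enumerates peptides with up to `max_missed` missed cleavages as unions of
#' adjacent fully-cleaved fragments.
#'
#' @param sequence Uppercase amino-acid string.
#' @param max_missed Maximum number of missed cleavages (>= 0).
#' @return Data frame with columns `peptide`, `missed_cleavages`, `start`,
#'   `end` (1-based positions in the input).
#' @export
digest_trypsin <- function(sequence, max_missed = 0) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0) {
    stop("sequence must be a non-empty string", call. = FALSE)
  }
  chars <- strsplit(sequence, "")[[1]]
  ok <- chars %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(ok)) {
    stop("invalid residue '", chars[which(!ok)[1]], "' at position ",
         which(!ok)[1], call. = FALSE)
  }
  n <- length(chars)
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, n)
  bounds <- unique(bounds)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  k_frag <- length(starts)
  out <- list()
  for (mc in 0:max_missed) {
    if (mc + 1L > k_frag) break
    for (i in seq_len(k_frag - mc)) {
      s <- starts[i]
      e <- ends[i + mc]
      out[[length(out) + 1L]] <- data.frame(
        peptide = substr(sequence, s, e),
        missed_cleavages = mc, start = s, end = e,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Select proteotypic peptide candidates for an SRM panel
#'
#' Applies, in order, the hard candidate filters used to assemble the
#' monitored panel: peptide length within `[min_length, max_length]`
#' residues; no missed cleavages; experimental candidates require a search
#' engine score above `min_score`; database-only candidates are admitted
#' only for proteins with no MS-detected candidate; peptides containing
#' residues prone to modification (default methionine and tryptophan) are
#' dropped when alternative peptides survive for the same protein. Survivors
#' are ranked preferring candidates supported by both experimental data and
#' public databases, then by descending evidence score, with a lexicographic
#' peptide tie-break, and truncated to `max_per_protein` peptides.
#'
#' @param candidates Data frame with columns `protein`, `peptide`,
#'   `evidence_score` (numeric or NA), `source` (one of `experimental`,
#'   `database`, `both`), `missed_cleavages`.
#' @param max_per_protein Maximum peptides retained per protein (default 4).
#' @param min_length,max_length Peptide length bounds in residues
#'   (default 8-25).
#' @param min_score Minimum search-engine score for MS-detected candidates
#'   (default 28, exclusive).
#' @param avoid_residues Residue blacklist applied when alternatives exist
#'   (default `c("M", "W")`).
#' @return Data frame of accepted candidates with a `rank` column
#'   (1 = best) within each protein.
#' @export
select_candidates <- function(candidates, max_per_protein = 4,
                              min_length = 8, max_length = 25,
                              min_score = 28, avoid_residues = c("M", "W")) {
  req <- c("protein", "peptide", "evidence_score", "source", "missed_cleavages")
  missing_cols <- setdiff(req, names(candidates))
  if (length(missing_cols) > 0) {
    stop("candidates table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(candidates$source %in% c("experimental", "database", "both"))) {
    stop("source must be experimental, database, or both", call. = FALSE)
  }
  ms_detected <- candidates$source %in% c("experimental", "both")
  if (any(ms_detected & is.na(candidates$evidence_score))) {
    stop("MS-detected candidates require an evidence_score", call. = FALSE)
  }
  pick_one <- function(df) {
    len <- nchar(df$peptide)
    df <- df[len >= min_length & len <= max_length, , drop = FALSE]
    df <- df[df$missed_cleavages == 0, , drop = FALSE]
    is_ms <- df$source %in% c("experimental", "both")
    df <- df[!is_ms | df$evidence_score > min_score, , drop = FALSE]
    # database-only candidates only when nothing was detected by MS
    if (any(df$source %in% c("experimental", "both"))) {
      df <- df[df$source != "database", , drop = FALSE]
    }
    if (nrow(df) == 0) return(df)
    if (length(avoid_residues) > 0) {
      pat <- paste0("[", paste(avoid_residues, collapse = ""), "]")
      flagged <- grepl(pat, df$peptide)
      if (any(!flagged)) df <- df[!flagged, , drop = FALSE]
    }
    src_rank <- ifelse(df$source == "both", 0L, 1L)
    score <- ifelse(is.na(df$evidence_score), -Inf, df$evidence_score)
    ord <- order(src_rank, -score, df$peptide)
    df <- df[ord, , drop = FALSE]
    df <- utils::head(df, max_per_protein)
    df$rank <- seq_len(nrow(df))
    df
  }
  parts <- lapply(split(candidates, candidates$protein), pick_one)
  parts <- parts[vapply(parts, nrow, integer(1)) > 0]
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- candidates[0, , drop = FALSE]
    out$rank <- integer(0)
  }
  rownames(out) <- NULL
  out
}
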