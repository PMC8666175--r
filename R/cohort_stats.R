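# Differential abundance across clinical conditions, FDR control, PCA and
# Ward clustering of protein abundance profiles.

.contrast_names <- c("HCC-control", "cirrhosis-control", "HCC-cirrhosis")

#' Test clinical-condition effects per protein
#'
#' Fits, for each protein, a least-squares linear model of normalized log2
#' abundance on clinical condition (with an optional blocking factor when
#' repeated measures per subject exist), reports the omnibus condition
#' F-test and the three pairwise contrasts with their own t-test p-values,
#' and attaches Benjamini-Hochberg q-values computed across proteins within
#' each contrast family. Missing cells are dropped row-wise per protein.
#' A protein with zero variance is returned with p = 1 and a
#' `zero_variance` flag; a protein with fewer than 2 non-missing values in
#' some condition is flagged untestable.
#'
#' @param mat [protein_matrix()] or matrix, samples x proteins.
#' @param metadata Data frame with `sample_id` and `condition`
#'   (control/cirrhosis/HCC); an optional `subject_id` column with repeated
#'   samples per subject adds a blocking factor.
#' @return Data frame with columns `protein`, `contrast` (`omnibus` or a
#'   pairwise difference), `effect` (log2 units, NA for omnibus),
#'   `statistic` (F for omnibus, t for contrasts), `p_value`, `q_value`,
#'   `flag`.
#' @export
fit_condition_model <- function(mat, metadata) {
  cond <- factor(metadata$condition[match(rownames(mat), metadata$sample_id)],
                 levels = .conditions)
  if (anyNA(cond)) {
    stop("every sample in the matrix needs a condition in the metadata",
         call. = FALSE)
  }
  block <- NULL
  if ("subject_id" %in% names(metadata)) {
    subj <- metadata$subject_id[match(rownames(mat), metadata$sample_id)]
    if (anyDuplicated(subj[!is.na(subj)])) block <- factor(subj)
  }
  rows <- list()
  for (prot in colnames(mat)) {
    y <- mat[, prot]
    keep <- !is.na(y)
    flag <- NA_character_
    est <- stats::setNames(rep(NA_real_, 3), .contrast_names)
    tstat <- est
    pvals <- est
    f_stat <- NA_real_
    f_p <- NA_real_
    counts <- table(cond[keep])
    if (any(counts < 2)) {
      flag <- "untestable"
    } else if (stats::var(y[keep]) == 0) {
      flag <- "zero_variance"
      f_p <- 1
      pvals[] <- 1
      est[] <- 0
    } else {
      df <- data.frame(y = y[keep], cond = droplevels(cond[keep]))
      if (!is.null(block)) df$block <- droplevels(block[keep])
      form <- if (!is.null(block) && nlevels(df$block) > 1) {
        y ~ block + cond
      } else {
        y ~ cond
      }
      fit <- stats::lm(form, data = df)
      an <- stats::anova(fit)
      f_stat <- an["cond", "F value"]
      f_p <- an["cond", "Pr(>F)"]
      if (is.na(f_p)) {
        flag <- "zero_variance"
        f_p <- 1
        pvals[] <- 1
        est[] <- 0
      } else {
        # pairwise contrasts from group means and pooled residual variance
        mse <- sum(stats::residuals(fit)^2) / fit$df.residual
        gm <- tapply(df$y, df$cond, mean)
        gn <- table(df$cond)
        pair <- list(`HCC-control` = c("HCC", "control"),
                     `cirrhosis-control` = c("cirrhosis", "control"),
                     `HCC-cirrhosis` = c("HCC", "cirrhosis"))
        for (cn in names(pair)) {
          a <- pair[[cn]][1]
          b <- pair[[cn]][2]
          if (!(a %in% names(gm)) || !(b %in% names(gm))) next
          est[cn] <- gm[[a]] - gm[[b]]
          se <- sqrt(mse * (1 / gn[[a]] + 1 / gn[[b]]))
          tstat[cn] <- est[cn] / se
          pvals[cn] <- 2 * stats::pt(-abs(tstat[cn]), fit$df.residual)
        }
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      protein = prot,
      contrast = c("omnibus", .contrast_names),
      effect = c(NA_real_, est),
      statistic = c(f_stat, tstat),
      p_value = c(f_p, pvals),
      flag = flag, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q_value <- NA_real_
  for (cn in unique(out$contrast)) {
    sel <- out$contrast == cn & !is.na(out$p_value)
    if (any(sel)) out$q_value[sel] <- benjamini_hochberg(out$p_value[sel])
  }
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjusted p-values, order-preserving in the
#' input.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return q-values of the same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Principal component analysis of a protein abundance matrix
#'
#' Proteins (columns) are centered to mean 0 and scaled to unit SD before
#' an exact singular value decomposition. Zero-variance proteins are
#' excluded with a warning (they carry no direction). The matrix must be
#' complete; apply an imputation policy first (see [impute_halfmin()]).
#'
#' @param mat Samples x proteins matrix, complete, >= 3 samples.
#' @return List with `scores` (samples x components), `loadings`
#'   (proteins x components), `var_explained` (fractions summing to 1).
#' @export
run_pca <- function(mat) {
  m <- unclass(mat)
  if (anyNA(m)) stop("PCA requires a complete matrix; impute first",
                     call. = FALSE)
  if (nrow(m) < 3) stop("PCA requires at least 3 samples", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("excluding zero-variance protein(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
    m <- m[, sds > 0, drop = FALSE]
  }
  x <- scale(m)
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  var_exp <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, var_explained = var_exp)
}

#' Impute missing cells with half the protein's minimum observed value
#'
#' Left-censored missingness (signals below the detection limit) is the
#' dominant mechanism for missing cells in targeted assays, so missing
#' values are replaced by half of the protein's minimum observed abundance.
#'
#' @param mat Samples x proteins matrix with possible NA cells.
#' @return Complete matrix of the same shape.
#' @export
impute_halfmin <- function(mat) {
  m <- unclass(mat)
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (any(miss) && !all(miss)) {
      m[miss, j] <- min(m[, j], na.rm = TRUE) / 2
    }
  }
  m
}

#' Ward hierarchical clustering of protein profiles
#'
#' Protein abundance profiles (columns, optionally centered/scaled) are
#' clustered by Ward's minimum-variance method on a Euclidean distance
#' matrix; the tree is cut at `k` clusters. `k` is a user choice (the
#' dendrogram is meant to be inspected), defaulting to 2.
#'
#' @param mat Samples x proteins matrix, complete.
#' @param k Number of clusters (default 2); must not exceed the number of
#'   proteins.
#' @param scale. Center and scale protein profiles first (default TRUE).
#' @return List with `hclust` (the dendrogram), `assignments` (named
#'   integer vector by protein), `newick` (the tree as a nested string).
#' @export
cluster_proteins <- function(mat, k = 2, scale. = TRUE) {
  m <- unclass(mat)
  if (anyNA(m)) stop("clustering requires a complete matrix", call. = FALSE)
  if (k > ncol(m)) {
    stop("k (", k, ") exceeds the number of proteins (", ncol(m), ")",
         call. = FALSE)
  }
  x <- if (scale.) scale(m) else m
  d <- stats::dist(t(x), method = "euclidean")
  hc <- stats::hclust(d, method = "ward.D2")
  assignments <- stats::cutree(hc, k = k)
  list(hclust = hc, assignments = assignments, newick = .hclust_newick(hc))
}

# Serialize an hclust tree as a Newick-style nested string with heights.
.hclust_newick <- function(hc) {
  lab <- hc$labels
  rec <- function(node) {
    if (node < 0) return(lab[-node])
    h <- hc$height[node]
    left <- rec(hc$merge[node, 1])
    right <- rec(hc$merge[node, 2])
    sprintf("(%s,%s):%.6g", left, right, h)
  }
  paste0(rec(nrow(hc$merge)), ";")
}
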