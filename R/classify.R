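# ANOVA-ranked nested biomarker panels evaluated with LDA, QDA, multinomial
# logistic regression and random forests under leave-one-out
# cross-validation. All algorithms run with fixed sensible defaults and no
# metaparameter tuning; model complexity is controlled by panel size.

.algorithms <- c("lda", "qda", "multinomial", "random_forest")

#' Rank proteins by one-way ANOVA p-value
#'
#' Each protein is tested with a one-way ANOVA F-test of abundance across
#' the class labels; proteins are ordered by ascending p-value with a
#' deterministic lexicographic tie-break on the protein name.
#' Zero-variance proteins receive p = 1 and rank last.
#'
#' @param mat Samples x proteins matrix (complete).
#' @param labels Factor of class labels, one per sample.
#' @return Data frame `protein`, `p_value`, `rank` in rank order.
#' @export
rank_proteins_anova <- function(mat, labels) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2 || any(table(labels) < 2)) {
    stop("need >= 2 classes with >= 2 samples each", call. = FALSE)
  }
  p <- vapply(colnames(mat), function(prot) {
    y <- mat[, prot]
    if (stats::var(y) == 0) return(1)
    an <- stats::anova(stats::lm(y ~ labels))
    pv <- an[["Pr(>F)"]][1]
    if (is.na(pv)) 1 else pv
  }, numeric(1))
  ord <- order(p, colnames(mat))
  data.frame(protein = colnames(mat)[ord], p_value = unname(p[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

# Fit one algorithm on training data and return class probabilities for
# newdata. Returns NULL when the fit is skipped (QDA singularity guard).
.fit_predict <- function(algorithm, train_x, train_y, new_x, seed) {
  classes <- levels(train_y)
  k <- ncol(train_x)
  colnames(train_x) <- paste0("V", seq_len(k))
  colnames(new_x) <- colnames(train_x)
  tr <- data.frame(train_x)
  nw <- data.frame(new_x)
  if (algorithm == "lda") {
    fit <- MASS::lda(train_x, grouping = train_y)
    post <- stats::predict(fit, new_x)$posterior
  } else if (algorithm == "qda") {
    if (any(table(train_y) < k + 1)) return(NULL)
    fit <- MASS::qda(train_x, grouping = train_y)
    post <- stats::predict(fit, new_x)$posterior
  } else if (algorithm == "multinomial") {
    tr$y <- train_y
    fit <- nnet::multinom(y ~ ., data = tr, trace = FALSE, maxit = 500)
    post <- stats::predict(fit, newdata = nw, type = "probs")
    if (is.null(dim(post))) {
      if (length(classes) == 2) {
        post <- cbind(1 - post, post)
        colnames(post) <- classes
      } else {
        post <- matrix(post, nrow = 1, dimnames = list(NULL, names(post)))
      }
    }
  } else if (algorithm == "random_forest") {
    set.seed(seed)
    fit <- randomForest::randomForest(train_x, y = train_y, ntree = 500)
    post <- stats::predict(fit, new_x, type = "prob")
  } else {
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  }
  post <- post[, classes, drop = FALSE]
  post
}

#' LOOCV accuracy grid over nested panels and algorithms
#'
#' For each panel size k, the panel is the top-k proteins by ANOVA ranking.
#' By default the ranking is recomputed inside each training fold so that
#' feature selection never sees the held-out sample; `rank_once = TRUE`
#' ranks once on the full data instead (the simpler protocol). Each
#' algorithm's out-of-sample accuracy is the fraction of correctly
#' predicted held-out samples over all n leave-one-out folds. QDA folds
#' where some training class has fewer samples than k+1 are skipped (the
#' class covariance would be singular) and recorded as warnings; its
#' accuracy is then computed over the completed folds.
#'
#' @param mat Samples x proteins matrix, complete.
#' @param labels Factor of class labels.
#' @param algorithms Subset of `lda`, `qda`, `multinomial`, `random_forest`.
#' @param max_panel Largest panel size (default: all proteins).
#' @param seed Integer seed for the seeded algorithms (random forest).
#' @param rank_once Rank on all data instead of per training fold.
#' @return List with `accuracy` (panel size x algorithm matrix, percent),
#'   `warnings` (character), `ranking` (full-data ranking for reference).
#' @export
evaluate_panels <- function(mat, labels, algorithms = .algorithms,
                            max_panel = ncol(mat), seed = 1,
                            rank_once = FALSE) {
  bad <- setdiff(algorithms, .algorithms)
  if (length(bad) > 0) {
    stop("unknown algorithm(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  labels <- droplevels(as.factor(labels))
  n <- nrow(mat)
  max_panel <- min(max_panel, ncol(mat))
  full_rank <- rank_proteins_anova(mat, labels)
  correct <- array(NA, dim = c(max_panel, length(algorithms), n),
                   dimnames = list(NULL, algorithms, NULL))
  warns <- character(0)
  for (i in seq_len(n)) {
    tr_x <- mat[-i, , drop = FALSE]
    tr_y <- labels[-i]
    rk <- if (rank_once) full_rank else rank_proteins_anova(tr_x, tr_y)
    for (k in seq_len(max_panel)) {
      panel <- rk$protein[seq_len(k)]
      tx <- tr_x[, panel, drop = FALSE]
      nx <- mat[i, panel, drop = FALSE]
      for (alg in algorithms) {
        post <- .fit_predict(alg, tx, tr_y, nx, seed = seed + i)
        if (is.null(post)) {
          warns <- c(warns, sprintf(
            "qda skipped: fold %d, panel size %d (class smaller than k+1)",
            i, k))
          next
        }
        pred <- colnames(post)[which.max(post[1, ])]
        correct[k, alg, i] <- pred == as.character(labels[i])
      }
    }
  }
  acc <- apply(correct, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else 100 * mean(v, na.rm = TRUE)
  })
  dimnames(acc) <- list(panel_size = seq_len(max_panel),
                        algorithm = algorithms)
  list(accuracy = acc, warnings = unique(warns), ranking = full_rank)
}

#' Full classification report for a chosen panel and algorithm
#'
#' Fits the model on all samples (in-sample accuracy), then collects
#' held-out class probabilities from leave-one-out cross-validation to
#' build the confusion matrix (true class by predicted class),
#' out-of-sample accuracy, and per-class one-vs-rest ROC curves with
#' trapezoidal AUC.
#'
#' @param mat Samples x proteins matrix, complete.
#' @param labels Factor of class labels (every class present).
#' @param panel Character vector of proteins (subset of columns).
#' @param algorithm One of `lda`, `qda`, `multinomial`, `random_forest`.
#' @param seed Integer seed.
#' @return Object of class `classification_report`: `algorithm`,
#'   `selected_panel`, `in_sample_accuracy`, `out_of_sample_accuracy`
#'   (percent), `confusion` (integer matrix), `auc` (named per class),
#'   `roc` (data frame of ROC coordinates), `probabilities` (LOOCV
#'   held-out posteriors).
#' @export
final_model_report <- function(mat, labels, panel, algorithm = "qda",
                               seed = 1) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) {
    stop("classification requires at least 2 classes present", call. = FALSE)
  }
  if (any(table(labels) == 0)) {
    stop("class absent from labels: ",
         paste(levels(labels)[table(labels) == 0], collapse = ", "),
         call. = FALSE)
  }
  missing_prot <- setdiff(panel, colnames(mat))
  if (length(missing_prot) > 0) {
    stop("panel protein(s) not in matrix: ",
         paste(missing_prot, collapse = ", "), call. = FALSE)
  }
  x <- mat[, panel, drop = FALSE]
  n <- nrow(x)
  classes <- levels(labels)
  in_post <- .fit_predict(algorithm, x, labels, x, seed = seed)
  if (is.null(in_post)) {
    stop("model could not be fitted on the full data (singular class ",
         "covariance); choose a smaller panel", call. = FALSE)
  }
  in_pred <- classes[apply(in_post, 1, which.max)]
  in_acc <- 100 * mean(in_pred == as.character(labels))
  post <- matrix(NA_real_, n, length(classes),
                 dimnames = list(rownames(x), classes))
  for (i in seq_len(n)) {
    p <- .fit_predict(algorithm, x[-i, , drop = FALSE], labels[-i],
                      x[i, , drop = FALSE], seed = seed + i)
    if (!is.null(p)) post[i, ] <- p[1, ]
  }
  usable <- stats::complete.cases(post)
  pred <- rep(NA_character_, n)
  pred[usable] <- classes[apply(post[usable, , drop = FALSE], 1, which.max)]
  confusion <- table(factor(as.character(labels)[usable], levels = classes),
                     factor(pred[usable], levels = classes))
  confusion <- matrix(as.integer(confusion), nrow = length(classes),
                      dimnames = list(true = classes, predicted = classes))
  oos_acc <- 100 * sum(diag(confusion)) / sum(confusion)
  auc <- stats::setNames(rep(NA_real_, length(classes)), classes)
  roc_rows <- list()
  for (cls in classes) {
    resp <- as.integer(as.character(labels)[usable] == cls)
    if (length(unique(resp)) < 2) next
    rc <- pROC::roc(response = resp, predictor = post[usable, cls],
                    levels = c(0, 1), direction = "<", quiet = TRUE)
    auc[cls] <- as.numeric(pROC::auc(rc))
    roc_rows[[cls]] <- data.frame(class = cls,
                                  specificity = rc$specificities,
                                  sensitivity = rc$sensitivities,
                                  stringsAsFactors = FALSE)
  }
  structure(list(
    algorithm = algorithm, selected_panel = panel,
    in_sample_accuracy = in_acc, out_of_sample_accuracy = oos_acc,
    confusion = confusion, auc = auc,
    roc = do.call(rbind, c(roc_rows, list(make.row.names = FALSE))),
    probabilities = post
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Classification report (%s, %d-protein panel)\n",
              x$algorithm, length(x$selected_panel)))
  cat("  panel:", paste(x$selected_panel, collapse = ", "), "\n")
  cat(sprintf("  in-sample accuracy:     %.2f%%\n", x$in_sample_accuracy))
  cat(sprintf("  out-of-sample accuracy: %.2f%%\n", x$out_of_sample_accuracy))
  cat("  per-class one-vs-rest AUC:\n")
  for (cls in names(x$auc)) {
    cat(sprintf("    %-10s %.4f\n", cls, x$auc[cls]))
  }
  cat("  confusion (true x predicted):\n")
  print(x$confusion)
  invisible(x)
}
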