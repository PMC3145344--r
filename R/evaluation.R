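# Interpatient evaluation: balanced classification rate, patient-disjoint
# splits and leave-one-patient-out hyperparameter search.

#' Balanced classification rate
#'
#' Summary of multiclass performance robust to class unbalance: the mean of
#' the per-class recalls (class accuracies). With four classes, a trivial
#' classifier that always predicts the majority class scores exactly 0.25 --
#' one class fully right, three fully wrong -- which reflects the unbalance
#' far better than the ~0.9 raw accuracy it would get. The arithmetic mean
#' is the default; a geometric-mean variant is provided for completeness
#' (it scores 0 as soon as any class is never predicted correctly).
#'
#' @param y_true True labels; every class present in `y_true` must be
#'   nonempty (it is, by construction).
#' @param y_pred Predicted labels, same length.
#' @param classes Class set; defaults to the classes present in `y_true`.
#'   A class listed here but absent from `y_true` is an error.
#' @param kind `"arithmetic"` (default) or `"geometric"`.
#' @return A single fraction in [0, 1].
#' @export
bcr <- function(y_true, y_pred, classes = NULL,
                kind = c("arithmetic", "geometric")) {
  kind <- match.arg(kind)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (is.null(classes)) classes <- sort(unique(y_true))
  n_k <- table(factor(y_true, levels = classes))
  if (any(n_k == 0)) stop("empty true class: ",
                          paste(classes[n_k == 0], collapse = ", "))
  recalls <- vapply(classes, function(k)
    mean(y_pred[y_true == k] == k), numeric(1))
  if (kind == "arithmetic") mean(recalls) else exp(mean(log(pmax(recalls, 0))))
}

#' Per-class evaluation report
#'
#' Confusion matrix, per-class accuracies (recalls) and BCR of a prediction.
#'
#' @inheritParams bcr
#' @return An object of class `evaluation_report`: `confusion` (true x
#'   predicted counts), `per_class_accuracy`, `bcr`, `n_beats`.
#' @export
evaluation_report <- function(y_true, y_pred, classes = NULL,
                              kind = c("arithmetic", "geometric")) {
  kind <- match.arg(kind)
  if (is.null(classes)) classes <- sort(unique(as.character(y_true)))
  tf <- factor(as.character(y_true), levels = classes)
  pf <- factor(as.character(y_pred), levels = union(classes, unique(as.character(y_pred))))
  confusion <- table(true = tf, predicted = pf)
  acc <- vapply(classes, function(k) mean(y_pred[y_true == k] == k), numeric(1))
  structure(list(confusion = confusion,
                 per_class_accuracy = acc,
                 bcr = bcr(y_true, y_pred, classes, kind),
                 n_beats = as.numeric(table(tf))),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("BCR: %.2f%%\n", 100 * x$bcr))
  cat("per-class accuracy:",
      paste(sprintf("%s=%.2f%%", names(x$per_class_accuracy),
                    100 * x$per_class_accuracy), collapse = "  "), "\n")
  print(x$confusion)
  invisible(x)
}

#' Split a multi-record feature matrix into patient-disjoint train and test
#'
#' Beats are grouped strictly by record (patient): no patient contributes to
#' both sides. A class-ratio report per side is attached so the
#' approximately-equal-prevalence property of a split can be audited.
#'
#' @param fm A `feature_matrix` covering all referenced records.
#' @param train_records,test_records Disjoint record id vectors.
#' @return A list with `train`, `test` (feature matrices) and `ratios`
#'   (class frequency table per side, each row summing to 1).
#' @export
split_interpatient <- function(fm, train_records, test_records) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!length(train_records) || !length(test_records))
    stop("both record lists must be nonempty")
  if (length(intersect(train_records, test_records)))
    stop("overlapping record ids: ",
         paste(intersect(train_records, test_records), collapse = ", "))
  missing <- setdiff(c(train_records, test_records), unique(fm$beats$record))
  if (length(missing)) stop("records not in the matrix: ",
                            paste(missing, collapse = ", "))
  take <- function(ids) {
    rows <- fm$beats$record %in% ids
    out <- fm
    out$x <- fm$x[rows, , drop = FALSE]
    out$mask <- fm$mask[rows, , drop = FALSE]
    out$beats <- fm$beats[rows, , drop = FALSE]
    out
  }
  tr <- take(train_records); te <- take(test_records)
  ratios <- rbind(train = prop.table(table(factor(tr$beats$label, levels = AAMI_CLASSES))),
                  test = prop.table(table(factor(te$beats$label, levels = AAMI_CLASSES))))
  list(train = tr, test = te, ratios = ratios)
}

#' Leave-one-patient-out hyperparameter search for the weighted SVM
#'
#' For every point of the (degree, C) grid, each patient of the training set
#' is left out in turn, the SVM is fitted on the remaining patients and the
#' BCR on the held-out patient is recorded; the grid point with the highest
#' mean fold BCR wins, ties resolved toward the smaller degree and then the
#' smaller C. A fold missing one of the classes is scored over the classes
#' it contains and flagged in the log.
#'
#' @param fm A fully imputed training `feature_matrix` (or numeric matrix).
#' @param y Labels per row.
#' @param patient_ids Patient id per row (defaults to the record column).
#' @param degrees Kernel degrees to try (protocol default 1:4).
#' @param costs Regularization values (protocol default 10^(-5:5)).
#' @param weights Class weights used in every fit; default inverse priors on
#'   the full training labels.
#' @param features Optional feature-name subset.
#' @param standardize Passed to [wsvm()].
#' @return A list of class `cv_result`: `best` (degree, cost), `log` (one
#'   row per grid point with mean BCR and incomplete-fold count).
#' @export
loo_patient_cv <- function(fm, y, patient_ids = NULL, degrees = 1:4,
                           costs = 10^(-5:5), weights = NULL,
                           features = NULL, standardize = FALSE) {
  x <- if (inherits(fm, "feature_matrix")) fm$x else as.matrix(fm)
  if (is.null(patient_ids))
    patient_ids <- if (inherits(fm, "feature_matrix")) fm$beats$record else
      stop("patient_ids required")
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  y <- as.character(y)
  if (is.null(weights)) weights <- inverse_prior_weights(y)
  pats <- unique(patient_ids)
  if (length(pats) < 2L) stop("need at least 2 patients")
  grid <- expand.grid(degree = degrees, cost = costs)
  log <- data.frame(grid, mean_bcr = NA_real_, incomplete_folds = 0L)
  for (g in seq_len(nrow(grid))) {
    fold_bcr <- numeric(length(pats)); inc <- 0L
    for (pi in seq_along(pats)) {
      tr <- patient_ids != pats[pi]
      present <- intersect(names(weights), unique(y[!tr]))
      if (length(present) < length(weights)) inc <- inc + 1L
      m <- wsvm(x[tr, , drop = FALSE], y[tr], degree = grid$degree[g],
                cost = grid$cost[g], weights = weights,
                standardize = standardize)
      pred <- predict(m, x[!tr, , drop = FALSE])
      fold_bcr[pi] <- bcr(y[!tr], pred, classes = present)
    }
    log$mean_bcr[g] <- mean(fold_bcr)
    log$incomplete_folds[g] <- inc
  }
  ord <- order(-log$mean_bcr, log$degree, log$cost)
  best <- log[ord[1], c("degree", "cost")]
  structure(list(best = best, log = log), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("loo-patient CV: best degree %g, C %g (mean BCR %.3f over %d grid points)\n",
              x$best$degree, x$best$cost,
              max(x$log$mean_bcr), nrow(x$log)))
  invisible(x)
}
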