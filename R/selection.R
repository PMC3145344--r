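# Feature selection: histogram mutual-information filter ranking and a
# forward-backward wrapper search driven by any classifier honouring the
# fit/predict contract.

#' Histogram estimate of the mutual information between a feature and the
#' class labels
#'
#' The feature is binned into `round(sqrt(N))` equal-width bins over its
#' observed range and the plug-in estimate
#' `I(x; y) = H(y) - sum_b p(b) H(y | bin b)`
#' is computed from the empirical frequencies, in natural log units (nats).
#' A constant feature yields a single effective bin and `I = 0`; small
#' negative values from numerical noise are clipped at 0.
#'
#' @param x Numeric feature vector (length >= 4).
#' @param y Class labels, same length.
#' @return A list of class `mi_score`: `mi_nats`, `n_bins`.
#' @export
histogram_mi <- function(x, y) {
  n <- length(x)
  if (n < 4L || length(y) != n) stop("need length(x) == length(y) >= 4")
  n_bins <- max(1L, as.integer(round(sqrt(n))))
  rng <- range(x)
  bins <- if (rng[1] == rng[2]) rep(1L, n) else {
    b <- floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L
    pmin(b, n_bins)                                # x == max falls in the last bin
  }
  yf <- factor(y)
  ent <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log(p))
  }
  h_y <- ent(table(yf))
  tab <- table(bins, yf)
  p_b <- rowSums(tab) / n
  h_y_given_x <- sum(p_b * apply(tab, 1, ent))
  structure(list(mi_nats = max(0, h_y - h_y_given_x), n_bins = n_bins),
            class = "mi_score")
}

#' @export
print.mi_score <- function(x, ...) {
  cat(sprintf("mi_score: %.4f nats (%d bins)\n", x$mi_nats, x$n_bins))
  invisible(x)
}

#' Rank features by mutual information with the class labels
#'
#' Scores every column of the (imputed) feature matrix with [histogram_mi()]
#' and sorts in decreasing order; ties keep the original column order. The
#' full ranking is returned; its head is the filter's feature choice.
#'
#' @param fm A `feature_matrix`, or a plain numeric matrix with column names.
#' @param y Class labels, one per row.
#' @return A data.frame `(rank, name, mi_nats, n_bins)` sorted by rank.
#' @export
rank_by_mi <- function(fm, y) {
  x <- if (inherits(fm, "feature_matrix")) fm$x else as.matrix(fm)
  if (anyNA(x)) stop("feature matrix must be fully imputed before ranking")
  mi <- vapply(seq_len(ncol(x)), function(j) histogram_mi(x[, j], y)$mi_nats,
               numeric(1))
  ord <- order(-mi, seq_along(mi))
  data.frame(rank = seq_along(ord), name = colnames(x)[ord], mi_nats = mi[ord],
             n_bins = max(1L, as.integer(round(sqrt(nrow(x))))))
}

#' Write an MI ranking as TSV (rank, name, mi_nats)
#' @param ranking Output of [rank_by_mi()].
#' @param path Output file.
#' @export
write_mi_ranking <- function(ranking, path) {
  utils::write.table(ranking[c("rank", "name", "mi_nats")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Forward-backward wrapper feature selection
#'
#' Greedy search driven by a classifier: starting from the empty set, each
#' forward step adds the feature whose addition gives the strictly highest
#' increase of the criterion; from the third step onward a backward pass
#' removes a previously selected feature whenever its removal strictly
#' increases the criterion. The search stops when no addition improves or
#' when `max_features` is reached.
#'
#' The default criterion is the balanced classification rate of the learner
#' on an internal patient-grouped split of the training data (a seeded 25%
#' of patients held out), so model selection never touches the test
#' patients.
#'
#' @param fm A fully imputed `feature_matrix` (or numeric matrix).
#' @param y Class labels per row.
#' @param learner Function `(x, y)` returning an object with a `predict`
#'   method; default [wlda()] with inverse-prior weights.
#' @param criterion Function `(features)` returning the scalar criterion for
#'   a character vector of feature names; default BCR on the internal split.
#' @param max_features Cap on the selected subset size (default 10).
#' @param patient_ids Needed by the default criterion (patient-grouped
#'   split); defaults to the feature matrix record column.
#' @param holdout Fraction of patients held out by the default criterion.
#' @param seed Seed for the internal split.
#' @return An object of class `selection_trace`: `steps` (data.frame of
#'   action/feature/criterion for accepted steps), `final_set`,
#'   `n_evaluations`.
#' @export
forward_backward <- function(fm, y, learner = NULL, criterion = NULL,
                             max_features = 10L, patient_ids = NULL,
                             holdout = 0.25, seed = 1L) {
  x <- if (inherits(fm, "feature_matrix")) fm$x else as.matrix(fm)
  if (anyNA(x)) stop("feature matrix must be fully imputed")
  if (max_features < 1L) stop("max_features must be >= 1")
  y <- as.character(y)
  if (is.null(learner))
    learner <- function(xt, yt) wlda(xt, yt, inverse_prior_weights(yt))
  if (is.null(criterion)) {
    if (is.null(patient_ids))
      patient_ids <- if (inherits(fm, "feature_matrix")) fm$beats$record else
        stop("patient_ids needed for the default patient-grouped criterion")
    pats <- unique(patient_ids)
    n_hold <- max(1L, round(holdout * length(pats)))
    if (length(pats) < 2L) stop("default criterion needs >= 2 patients")
    hold_pats <- with_local_seed(seed, sample(pats, n_hold))
    tr <- !(patient_ids %in% hold_pats); va <- !tr
    criterion <- function(features) {
      m <- learner(x[tr, features, drop = FALSE], y[tr])
      bcr(y[va], predict(m, x[va, features, drop = FALSE]))
    }
  }
  all_feats <- colnames(x)
  sel <- character(0)
  best <- -Inf
  steps <- list()
  n_eval <- 0L
  repeat {
    cand <- setdiff(all_feats, sel)
    if (!length(cand) || length(sel) >= max_features) break
    vals <- vapply(cand, function(f) {
      n_eval <<- n_eval + 1L
      tryCatch(criterion(c(sel, f)), error = function(e)
        stop("criterion evaluation failed for feature '", f, "': ",
             conditionMessage(e)))
    }, numeric(1))
    if (max(vals) <= best) break                     # strict improvement required
    add <- cand[which.max(vals)]
    sel <- c(sel, add); best <- max(vals)
    steps[[length(steps) + 1L]] <- data.frame(action = "add", feature = add,
                                              criterion = best)
    if (length(sel) >= 3L) {                         # backward pass
      repeat {
        rem_vals <- vapply(sel, function(f) {
          n_eval <<- n_eval + 1L
          criterion(setdiff(sel, f))
        }, numeric(1))
        if (max(rem_vals) <= best) break
        drop <- sel[which.max(rem_vals)]
        sel <- setdiff(sel, drop); best <- max(rem_vals)
        steps[[length(steps) + 1L]] <- data.frame(action = "remove",
                                                  feature = drop,
                                                  criterion = best)
        if (length(sel) < 3L) break
      }
    }
  }
  structure(list(steps = do.call(rbind, steps), final_set = sel,
                 n_evaluations = n_eval),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("selection_trace: %d accepted steps, %d evaluations, final set (%d): %s\n",
              if (is.null(x$steps)) 0L else nrow(x$steps), x$n_evaluations,
              length(x$final_set), paste(x$final_set, collapse = ", ")))
  invisible(x)
}

#' Write a selection trace as JSON
#' @param trace A `selection_trace`.
#' @param path Output JSON path.
#' @export
write_trace_json <- function(trace, path) {
  jsonlite::write_json(list(steps = trace$steps, final_set = trace$final_set,
                            n_evaluations = trace$n_evaluations),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
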