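# Class-weighted classifiers for unbalanced beat classes.
#
# wlda: Gaussian classes with a shared covariance, estimated with per-class
# weights c_k so minority classes count more:
#   mu_k = class means,
#   Sigma = sum_k c_k S_k / sum_k c_k N_k,   S_k = within-class scatter,
# and prediction by the largest linear discriminant
#   f_k(x) = -1/2 mu_k' Sigma^-1 mu_k + mu_k' Sigma^-1 x,
# i.e. the smallest Mahalanobis distance between x and the class means.
#
# wsvm: soft-margin SVM whose slack penalty is split per class
# (c_+1 sum xi + c_-1 sum xi), polynomial kernel (x'z + 1)^d, one-against-one
# for K > 2. The quadratic program is solved by the libsvm backend (e1071);
# the weighting contract and the surface here are the package's.

#' Inverse-prior class weights
#'
#' Default class weights: the inverse of the class priors on the training
#' labels, normalized to sum to the number of classes (the normalization is
#' scale-irrelevant for the LDA covariance; for the SVM the scale folds into
#' the regularization parameter C).
#'
#' @param y Training labels.
#' @param classes Class set (defaults to the sorted unique labels).
#' @return Named positive weights, one per class.
#' @export
inverse_prior_weights <- function(y, classes = sort(unique(y))) {
  n_k <- table(factor(y, levels = classes))
  if (any(n_k == 0)) stop("class absent from y: ",
                          paste(classes[n_k == 0], collapse = ", "))
  w <- length(y) / as.numeric(n_k)
  w <- w / sum(w) * length(classes)
  stats::setNames(w, classes)
}

#' Fit a class-weighted linear discriminant classifier
#'
#' Closed-form estimation: per-class sample means and the weighted pooled
#' within-class scatter `Sigma = sum_k c_k S_k / sum_k c_k N_k`. With equal
#' weights this is exactly the maximum-likelihood pooled covariance of
#' ordinary LDA. If `Sigma` is singular a ridge
#' `1e-8 * trace(Sigma)/p * I` is added (correlated features are the known
#' LDA failure mode this guards against).
#'
#' @param x Numeric matrix (observations x features), no missing values.
#' @param y Labels; every class in `weights` must be present.
#' @param weights Named per-class weights `c_k`; default inverse priors.
#' @param ridge Relative ridge applied on singularity.
#' @return An object of class `wlda` with components `means` (K x p),
#'   `sigma`, `sigma_inv`, `weights`, `classes`, `counts`, `ridge_applied`.
#' @export
wlda <- function(x, y, weights = inverse_prior_weights(y), ridge = 1e-8) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  if (anyNA(x)) stop("x contains missing values; impute first")
  y <- as.character(y)
  classes <- names(weights)
  if (is.null(classes)) { classes <- sort(unique(y)); names(weights) <- classes }
  if (length(classes) < 2L) stop("need at least 2 classes")
  n_k <- table(factor(y, levels = classes))
  if (any(n_k == 0)) stop("class absent from y: ",
                          paste(classes[n_k == 0], collapse = ", "))
  p <- ncol(x)
  means <- matrix(0, length(classes), p, dimnames = list(classes, colnames(x)))
  scatter <- matrix(0, p, p)
  for (k in classes) {
    xk <- x[y == k, , drop = FALSE]
    means[k, ] <- colMeans(xk)
    d <- sweep(xk, 2, means[k, ])
    scatter <- scatter + weights[[k]] * crossprod(d)
  }
  sigma <- scatter / sum(weights * as.numeric(n_k))
  ridge_applied <- FALSE
  sigma_inv <- tryCatch(solve(sigma), error = function(e) NULL)
  if (is.null(sigma_inv) || rcond(sigma) < 1e-12) {
    sigma <- sigma + diag(ridge * sum(diag(sigma)) / p + .Machine$double.eps, p)
    sigma_inv <- solve(sigma)
    ridge_applied <- TRUE
  }
  structure(list(means = means, sigma = sigma, sigma_inv = sigma_inv,
                 weights = weights, classes = classes,
                 counts = as.numeric(n_k), ridge_applied = ridge_applied),
            class = "wlda")
}

#' @export
print.wlda <- function(x, ...) {
  cat(sprintf("wlda: %d classes (%s), %d features%s\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              ncol(x$means), if (x$ridge_applied) ", ridged covariance" else ""))
  cat("class weights:", paste(sprintf("%s=%.3g", x$classes, x$weights), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.wlda <- function(object, ...) {
  # discriminant f_k(x) = a_k + b_k' x
  b <- object$means %*% object$sigma_inv
  a <- -0.5 * rowSums(b * object$means)
  cbind(intercept = a, b)
}

#' Predict AAMI classes with a fitted wlda model
#'
#' Assigns each observation to the class with the largest discriminant
#' `f_k(x) = -1/2 mu_k' Sigma^-1 mu_k + mu_k' Sigma^-1 x`; ties go to the
#' lowest class index.
#'
#' @param object A [wlda] fit.
#' @param newdata Numeric matrix with the training dimensionality.
#' @param type `"class"` (default) or `"scores"` for the discriminant matrix.
#' @param ... Unused.
#' @export
predict.wlda <- function(object, newdata, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$means))
    stop("newdata has ", ncol(newdata), " features, model expects ", ncol(object$means))
  b <- object$means %*% object$sigma_inv          # K x p
  a <- -0.5 * rowSums(b * object$means)           # K
  scores <- sweep(newdata %*% t(b), 2, a, "+")    # n x K
  colnames(scores) <- object$classes
  if (type == "scores") return(scores)
  object$classes[max.col(scores, ties.method = "first")]
}

#' @export
summary.wlda <- function(object, ...) {
  print(object)
  cat("class counts:", paste(sprintf("%s=%d", object$classes, object$counts),
                             collapse = " "), "\n")
  invisible(object)
}

#' Fit a class-weighted one-against-one polynomial-kernel SVM
#'
#' For each unordered class pair a soft-margin SVM with polynomial kernel
#' `(x'z + 1)^degree` is fitted; the slack penalty of class k is
#' `C * c_k`, so minority classes are costlier to misclassify. Prediction is
#' by one-against-one majority vote with ties resolved toward the lowest
#' class index. The quadratic programs are solved by the libsvm backend.
#'
#' @param x Numeric matrix (observations x features), finite values.
#' @param y Labels.
#' @param degree Polynomial kernel degree (the protocol searches 1..4).
#' @param cost Regularization parameter C (protocol grid 1e-5..1e5).
#' @param weights Named per-class weights; default inverse priors.
#' @param standardize Standardize features to training mean/sd inside the
#'   model (off by default; the reference pipeline can enable it).
#' @return An object of class `wsvm`.
#' @export
wsvm <- function(x, y, degree = 2, cost = 1, weights = inverse_prior_weights(y),
                 standardize = FALSE) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("x must be finite; impute first")
  classes <- names(weights)
  yf <- factor(as.character(y), levels = classes)
  if (anyNA(yf)) stop("labels outside the weighted class set")
  if (any(table(yf) == 0)) stop("class absent from y: ",
                                paste(classes[table(yf) == 0], collapse = ", "))
  fit <- e1071::svm(x, yf, type = "C-classification", kernel = "polynomial",
                    degree = degree, gamma = 1, coef0 = 1, cost = cost,
                    class.weights = weights, scale = standardize)
  structure(list(fit = fit, classes = classes, degree = degree, cost = cost,
                 weights = weights, standardize = standardize),
            class = "wsvm")
}

#' @export
print.wsvm <- function(x, ...) {
  cat(sprintf("wsvm: degree %g, C %g, %d classes (%s), %d support vectors\n",
              x$degree, x$cost, length(x$classes),
              paste(x$classes, collapse = ", "), x$fit$tot.nSV))
  invisible(x)
}

#' @rdname wsvm
#' @param object A `wsvm` fit.
#' @param newdata Numeric matrix.
#' @param ... Unused.
#' @export
predict.wsvm <- function(object, newdata, ...) {
  as.character(predict(object$fit, as.matrix(newdata)))
}

#' Serialize / restore a wlda model as documented JSON
#' @param model A [wlda] fit.
#' @param path Output JSON path.
#' @return `path` invisibly; `read_wlda_json` returns the model.
#' @export
write_wlda_json <- function(model, path) {
  stopifnot(inherits(model, "wlda"))
  jsonlite::write_json(
    list(type = "wlda", classes = model$classes,
         weights = as.list(model$weights),
         means = model$means, sigma = model$sigma,
         ridge_applied = model$ridge_applied),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_wlda_json
#' @export
read_wlda_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  means <- as.matrix(j$means); rownames(means) <- j$classes
  sigma <- as.matrix(j$sigma)
  structure(list(means = means, sigma = sigma, sigma_inv = solve(sigma),
                 weights = unlist(j$weights), classes = j$classes,
                 counts = NA, ridge_applied = isTRUE(j$ridge_applied)),
            class = "wlda")
}
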