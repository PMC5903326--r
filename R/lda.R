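# Two-class linear discriminant analysis with equal priors and pooled
# covariance: w = Sp^-1 (mu_MI - mu_REST), boundary at the midpoint of the
# projected class means. Used both inside the swarm fitness and as the final
# classifier. A diagonal ridge fallback handles singular pooled covariances.

# solve Sp x = b, escalating a relative ridge until the system is
# well-posed; returns the solution and the ridge actually used
solve_pooled <- function(Sp, b, shrinkage = 1e-6) {
  lam <- 0
  scale <- mean(diag(Sp))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  repeat {
    S <- if (lam > 0) Sp + lam * scale * diag(nrow(Sp)) else Sp
    x <- tryCatch(
      backsolve(R <- chol(S), forwardsolve(t(R), b)),
      error = function(e) NULL
    )
    if (!is.null(x) && all(is.finite(x))) {
      return(list(x = drop(x), shrinkage = lam))
    }
    lam <- if (lam == 0) shrinkage else lam * 100
    if (lam > 1) abort("pooled covariance is irreparably singular")
  }
}

#' Fit a two-class linear discriminant classifier
#'
#' @param x Numeric matrix (samples x features) or a feature tibble from
#'   [extract_features()].
#' @param y Class labels; coerced to factor with levels `REST`, `MI`
#'   (MI is the positive class). Taken from the `label` column when `x` is a
#'   feature tibble.
#' @param shrinkage Initial relative diagonal ridge used only if the pooled
#'   covariance is singular; the engagement is reported in the fitted object.
#' @return A `bci_lda` object with `weights`, `bias`, and `levels`; the
#'   decision rule is MI iff `x %*% weights + bias > 0`, with a score of
#'   exactly 0 resolving to REST (conservative for orthosis activation).
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(40, -1), 20), matrix(rnorm(40, 1), 20))
#' fit <- lda_train(x, rep(c("REST", "MI"), each = 20))
#' fit$weights
lda_train <- function(x, y = NULL, shrinkage = 1e-6) {
  if (is.data.frame(x)) {
    y <- y %||% x$label
    x <- feature_matrix(x)
  }
  x <- as.matrix(x)
  y <- factor(y, levels = c("REST", "MI"))
  if (anyNA(y)) abort("labels must be REST or MI")
  n0 <- sum(y == "REST"); n1 <- sum(y == "MI")
  if (n0 < 2 || n1 < 2) {
    abort("both classes must be present with at least 2 samples each")
  }
  x0 <- x[y == "REST", , drop = FALSE]
  x1 <- x[y == "MI", , drop = FALSE]
  mu0 <- colMeans(x0); mu1 <- colMeans(x1)
  Sp <- ((n0 - 1) * stats::cov(x0) + (n1 - 1) * stats::cov(x1)) / (n0 + n1 - 2)
  sol <- solve_pooled(Sp, mu1 - mu0, shrinkage)
  if (sol$shrinkage > 0) {
    inform(sprintf("singular pooled covariance: ridge %.1e engaged", sol$shrinkage))
  }
  w <- sol$x
  structure(
    list(weights = w,
         bias = -sum(w * (mu0 + mu1) / 2),
         levels = c("REST", "MI"),
         feature_names = colnames(x),
         shrinkage_used = sol$shrinkage,
         n = c(REST = n0, MI = n1)),
    class = "bci_lda"
  )
}

#' Predict classes or decision scores from a fitted LDA
#'
#' @param object A `bci_lda` model.
#' @param newdata Matrix or feature tibble with the model's features.
#' @param type `"class"` (default) or `"score"`.
#' @param ... Unused.
#' @return Factor of predicted labels, or numeric scores.
#' @export
predict.bci_lda <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    miss <- setdiff(object$feature_names, names(newdata))
    if (length(miss)) {
      abort(paste0("newdata lacks model features: ", paste(miss, collapse = ", ")))
    }
    newdata <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  }
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$weights)) {
    abort(sprintf("feature dimension mismatch: model has %d, data has %d",
                  length(object$weights), ncol(newdata)))
  }
  score <- drop(newdata %*% object$weights) + object$bias
  if (type == "score") return(score)
  factor(ifelse(score > 0, "MI", "REST"), levels = object$levels)
}

#' Percentage classification accuracy
#'
#' @param predicted,truth Equal-length label vectors.
#' @return `100 * correct / total`.
#' @export
accuracy_pct <- function(predicted, truth) {
  if (length(predicted) == 0) abort("cannot compute accuracy of empty input")
  if (length(predicted) != length(truth)) abort("length mismatch")
  100 * mean(as.character(predicted) == as.character(truth))
}

#' @export
print.bci_lda <- function(x, ...) {
  cat(sprintf("<bci_lda> %d features, classes %s; bias %.4g\n",
              length(x$weights), paste(x$levels, collapse = "/"), x$bias))
  invisible(x)
}
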