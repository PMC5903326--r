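# Common spatial patterns per subband: W = eig(S1, S1 + S2), where S1 and S2
# are the trace-normalized average covariance matrices of the MI and REST
# windows. Solved by whitening S1 + S2, so W' (S1 + S2) W = I exactly and the
# generalized eigenvalues lie in [0, 1].

window_cov <- function(X) {
  C <- tcrossprod(X) # channels x channels; bandpassed signals are zero-mean
  C / sum(diag(C))
}

#' Class covariance matrices for one subband
#'
#' Averages trace-normalized per-window covariance matrices within each
#' class. `S1` is the MI covariance, `S2` the REST covariance.
#'
#' @param banded An `eeg_banded` object.
#' @param band Band index.
#' @return List with symmetric positive semi-definite `S1` and `S2`.
#' @export
estimate_class_covariances <- function(banded, band = 1) {
  stopifnot(inherits(banded, "eeg_banded"))
  lab <- banded$label
  if (nlevels(droplevels(lab)) < 2 || min(table(lab)) < 2) {
    abort("need at least two windows of each class (REST and MI)")
  }
  avg_cov <- function(idx) {
    covs <- lapply(idx, function(i) window_cov(banded$data[i, band, , ]))
    Reduce(`+`, covs) / length(covs)
  }
  list(S1 = avg_cov(which(lab == "MI")),
       S2 = avg_cov(which(lab == "REST")))
}

#' CSP spatial filters from a pair of class covariances
#'
#' Solves the generalized eigenproblem `S1 w = lambda (S1 + S2) w` by
#' whitening. Columns of `W` are spatial filters ordered by descending
#' eigenvalue; eigenvalues lie in `[0, 1]` and `W' (S1 + S2) W = I`.
#'
#' @param S1,S2 Symmetric positive semi-definite class covariance matrices
#'   (MI and REST).
#' @param reg_eps Relative ridge added to `S1 + S2` when it is
#'   ill-conditioned (triggered when the condition number exceeds `1e10`).
#' @return List with `W` (channels x channels) and `eigenvalues` (descending).
#' @export
compute_spatial_filters <- function(S1, S2, reg_eps = 1e-8) {
  check_sym <- function(S, nm) {
    if (!is.matrix(S) || nrow(S) != ncol(S) ||
        max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S)))) {
      abort(sprintf("%s must be a symmetric matrix", nm))
    }
  }
  check_sym(S1, "S1"); check_sym(S2, "S2")
  C <- S1 + S2
  ec <- eigen((C + t(C)) / 2, symmetric = TRUE)
  dvals <- ec$values
  if (min(dvals) <= 0 || max(dvals) / min(dvals) > 1e10) {
    inform("regularizing ill-conditioned S1 + S2 with a relative ridge")
    C <- C + reg_eps * mean(diag(C)) * diag(nrow(C))
    ec <- eigen((C + t(C)) / 2, symmetric = TRUE)
    dvals <- ec$values
  }
  P <- diag(1 / sqrt(dvals)) %*% t(ec$vectors) # whitener: P C P' = I
  G <- P %*% S1 %*% t(P)
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  W <- t(P) %*% eg$vectors
  list(W = W, eigenvalues = eg$values)
}

#' Fit per-subband CSP filters
#'
#' @param banded An `eeg_banded` object (training windows only; compute this
#'   on the training partition to avoid leakage).
#' @return A `csp_bank` object: per-band projection matrices `W`, descending
#'   `eigenvalues`, and the class covariances they came from.
#' @export
fit_csp_bank <- function(banded) {
  stopifnot(inherits(banded, "eeg_banded"))
  nb <- dim(banded$data)[2]
  fits <- lapply(seq_len(nb), function(b) {
    S <- estimate_class_covariances(banded, b)
    c(compute_spatial_filters(S$S1, S$S2), S)
  })
  structure(
    list(W = lapply(fits, `[[`, "W"),
         eigenvalues = lapply(fits, `[[`, "eigenvalues"),
         S1 = lapply(fits, `[[`, "S1"),
         S2 = lapply(fits, `[[`, "S2"),
         band_edges = banded$band_edges,
         channel_names = banded$channel_names),
    class = "csp_bank"
  )
}

#' @export
print.csp_bank <- function(x, ...) {
  cat(sprintf("<csp_bank> %d bands x %d spatial filters\n",
              length(x$W), ncol(x$W[[1]])))
  invisible(x)
}

#' Log-variance CSP features for every window
#'
#' Feature `(band b, filter j)` of a window is
#' `log(var_j / sum_k var_k)` where `var_j` is the variance of the window
#' projected through the j-th spatial filter of band b and the sum runs over
#' the projections used in that band. Columns are band-major and named
#' `band_<b>_filter_<j>`.
#'
#' The filters must come from training windows only; this function never
#' recomputes them from the windows it featurizes.
#'
#' @param banded An `eeg_banded` object.
#' @param bank A `csp_bank` fitted with [fit_csp_bank()].
#' @param columns Optional integer vector of filter columns to use per band
#'   (default: all). The broadband CSP baseline uses the first and last `m`.
#' @param log Logical: return log variance ratios (default) or raw ratios.
#' @return A tibble with `trial`, `label` and one column per feature, plus a
#'   `"layout"` attribute recording bands x filters.
#' @export
extract_features <- function(banded, bank, columns = NULL, log = TRUE) {
  stopifnot(inherits(banded, "eeg_banded"), inherits(bank, "csp_bank"))
  nb <- length(bank$W)
  stopifnot(dim(banded$data)[2] == nb)
  nw <- dim(banded$data)[1]
  ns <- dim(banded$data)[4]
  cols <- columns %||% seq_len(ncol(bank$W[[1]]))
  nf <- length(cols)

  feats <- matrix(0, nw, nb * nf)
  floored <- FALSE
  for (b in seq_len(nb)) {
    Wb <- bank$W[[b]][, cols, drop = FALSE]
    # project all windows at once: channels x (samples * windows)
    Xb <- matrix(aperm(banded$data[, b, , , drop = FALSE], c(3, 4, 1, 2)),
                 nrow = dim(banded$data)[3])
    P <- crossprod(Wb, Xb) # nf x (samples * windows)
    P3 <- array(P, dim = c(nf, ns, nw))
    mu <- colMeans(aperm(P3, c(2, 1, 3))) # nf x nw means over samples
    v <- apply(P3, c(1, 3), function(s) sum(s^2))
    v <- v - ns * mu^2 # nf x nw sums of squared deviations
    tot <- colSums(v)
    ratio <- sweep(v, 2, tot, "/")
    if (any(ratio < .Machine$double.eps)) {
      floored <- TRUE
      ratio <- pmax(ratio, .Machine$double.eps)
    }
    feats[, (b - 1) * nf + seq_len(nf)] <- t(if (log) base::log(ratio) else ratio)
  }
  if (floored) warn("zero-variance projection: feature floored at machine epsilon ratio")

  colnames(feats) <- as.vector(vapply(
    seq_len(nb),
    function(b) sprintf("band_%d_filter_%d", b, cols),
    character(nf)
  ))
  out <- tibble::as_tibble(as.data.frame(feats))
  out <- tibble::add_column(out,
                            trial = banded$trial, label = banded$label,
                            .before = 1)
  attr(out, "layout") <- feature_layout(n_bands = nb, n_filters = nf)
  out
}

# feature-matrix helpers: feature columns are everything named band_*
feature_matrix <- function(features) {
  as.matrix(features[, grepl("^band_", names(features)), drop = FALSE])
}
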