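# ggplot2 displays for result objects.

#' Plot cross-validation accuracies against the chance line
#'
#' @param object A `bci_cv` object.
#' @param ... Unused.
#' @return A ggplot: fold-level %CA distribution with the practical level of
#'   chance as a dotted line.
#' @export
autoplot.bci_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$ca_pct)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.3, size = 0.8) +
    ggplot2::geom_hline(yintercept = object$chance_pct, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "%CA",
                  title = "Cross-validated classification accuracy",
                  subtitle = sprintf("dotted line: practical level of chance (%.1f%%)",
                                     object$chance_pct)) +
    ggplot2::theme_minimal()
}

#' Compare methods' fold-level accuracies
#'
#' @param ... Named `bci_cv` objects.
#' @return A ggplot with one box per method and the chance line.
#' @export
plot_method_comparison <- function(...) {
  cvs <- list(...)
  if (is.null(names(cvs)) || any(names(cvs) == "")) {
    names(cvs) <- vapply(cvs, `[[`, character(1), "method")
  }
  df <- purrr::imap_dfr(cvs, function(cv, nm) {
    dplyr::mutate(tidy(cv), method = nm)
  })
  chance <- cvs[[1]]$chance_pct
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$ca_pct)) +
    ggplot2::geom_boxplot(width = 0.5, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.3, size = 0.8) +
    ggplot2::geom_hline(yintercept = chance, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "%CA") +
    ggplot2::theme_minimal()
}

#' Plot the swarm's best-fitness trace
#'
#' @param object A `pso_selection` object.
#' @param ... Unused.
#' @return A ggplot of best fitness per generation.
#' @export
autoplot.pso_selection <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$generation, y = .data$best_fitness)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "generation", y = "best fitness",
                  title = "Swarm convergence") +
    ggplot2::theme_minimal()
}

#' Plot per-run trigger rates of an online session
#'
#' @param object A `bci_session` object.
#' @param ... Unused.
#' @return A ggplot of per-run %CT (bar height), with the session %CT as a
#'   dashed line.
#' @export
autoplot.bci_session <- function(object, ...) {
  ggplot2::ggplot(object$runs,
                  ggplot2::aes(x = factor(.data$run), y = .data$ct_pct)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_hline(yintercept = object$ct_pct, linetype = "dashed") +
    ggplot2::labs(x = "run", y = "%CT",
                  title = "Orthosis trigger rate per run",
                  subtitle = sprintf("session: %%CA %.1f, %%CT %.1f",
                                     object$ca_pct, object$ct_pct)) +
    ggplot2::theme_minimal()
}
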