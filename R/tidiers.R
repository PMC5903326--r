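# broom-style tidiers.

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy cross-validation results
#'
#' @param x A `bci_cv` object.
#' @param ... Unused.
#' @return Per-fold tibble: `method`, `repetition`, `fold`, `ca_pct`,
#'   `n_selected`, `fitness`.
#' @export
tidy.bci_cv <- function(x, ...) {
  tibble::add_column(x$results, method = x$method, .before = 1)
}

#' One-row summary of a cross-validation run
#'
#' @param x A `bci_cv` object.
#' @param ... Unused.
#' @export
glance.bci_cv <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_folds = max(x$results$fold),
    n_repetitions = max(x$results$repetition),
    mean_ca = x$mean_ca,
    sd_ca = x$sd_ca,
    chance_pct = x$chance_pct,
    above_chance = x$mean_ca > x$chance_pct
  )
}

#' Tidy a fitted linear discriminant
#'
#' @param x A `bci_lda` object.
#' @param ... Unused.
#' @return Tibble of terms (features plus `(Bias)`) and estimates.
#' @export
tidy.bci_lda <- function(x, ...) {
  tibble::tibble(
    term = c(x$feature_names %||% paste0("f", seq_along(x$weights)), "(Bias)"),
    estimate = c(x$weights, x$bias)
  )
}

#' @export
glance.bci_lda <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$weights),
    n_rest = unname(x$n["REST"]),
    n_mi = unname(x$n["MI"]),
    shrinkage_used = x$shrinkage_used
  )
}

#' Tidy a swarm feature-selection run
#'
#' @param x A `pso_selection` object.
#' @param ... Unused.
#' @return The per-generation best-fitness trace.
#' @export
tidy.pso_selection <- function(x, ...) x$history

#' @export
glance.pso_selection <- function(x, ...) {
  tibble::tibble(
    best_fitness = x$best_fitness,
    best_err = x$best_err,
    n_selected = sum(x$mask),
    n_features = x$layout$D,
    n_generations = nrow(x$history),
    early_stop = nrow(x$history) < x$config$n_generations
  )
}

#' Tidy an online session
#'
#' @param x A `bci_session` object.
#' @param ... Unused.
#' @return Window-level event log: `trial`, `run`, `window`, `truth`,
#'   `prediction`, `correct`.
#' @export
tidy.bci_session <- function(x, ...) x$windows

#' @export
glance.bci_session <- function(x, ...) {
  tibble::tibble(
    n_trials = nrow(x$trials),
    n_windows = nrow(x$windows),
    ca_pct = x$ca_pct,
    ct_pct = x$ct_pct,
    mean_window_time_s = x$mean_window_time_s
  )
}
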