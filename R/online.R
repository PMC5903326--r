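# Online-session simulator: each 8-s trial is replayed as six consecutive
# 1-s windows ([0,1) ... [5,6) s; the first three fall in the rest interval,
# the next three in the MI interval). Every window runs through exactly the
# offline path — notch + filter bank, frozen CSP projections, the frozen
# feature mask, the frozen LDA — and the orthosis trigger fires iff at least
# 2 of the 3 MI windows are classified as MI.

#' Online protocol
#'
#' @param trials_per_run Trials per run.
#' @param runs_per_session Runs per session.
#' @param n_windows Consecutive 1-s windows analysed per trial.
#' @param n_rest How many of those windows are REST (the leading ones).
#' @param trigger_votes MI votes (out of the MI windows) required to trigger
#'   the orthosis.
#' @return An `online_protocol` object.
#' @export
online_protocol <- function(trials_per_run = 20,
                            runs_per_session = 3,
                            n_windows = 6,
                            n_rest = 3,
                            trigger_votes = 2) {
  stopifnot(n_rest < n_windows, trigger_votes >= 1,
            trigger_votes <= n_windows - n_rest)
  structure(
    list(trials_per_run = trials_per_run,
         runs_per_session = runs_per_session,
         n_windows = n_windows, n_rest = n_rest,
         trigger_votes = trigger_votes),
    class = "online_protocol"
  )
}

#' Orthosis trigger decision
#'
#' The robotic orthosis is activated immediately after the MI interval iff
#' at least `votes` of the MI-window classification outputs are MI. REST
#' windows never influence the trigger.
#'
#' @param mi_predictions Predicted labels of the MI windows (character or
#'   factor), or a logical vector of MI votes.
#' @param votes Minimum MI votes required.
#' @return Logical: whether the orthosis triggers.
#' @export
#' @examples
#' trigger_decision(c("MI", "MI", "REST")) # fires
#' trigger_decision(c("REST", "REST", "REST")) # does not
trigger_decision <- function(mi_predictions, votes = 2) {
  hits <- if (is.logical(mi_predictions)) {
    mi_predictions
  } else {
    as.character(mi_predictions) == "MI"
  }
  sum(hits) >= votes
}

# classify an array of raw 1-s windows (windows x channels x samples) with a
# frozen model — the single path shared by offline evaluation replays and
# the online simulator
classify_windows <- function(model, win_data, label = NULL, trial = NULL) {
  nw <- dim(win_data)[1]
  wins <- as_eeg_windows(
    win_data,
    label = label %||% factor(rep("REST", nw), levels = c("REST", "MI")),
    trial = trial %||% seq_len(nw),
    fs = model$sampling_rate,
    channel_names = model$channel_names
  )
  banded <- apply_filter_bank(wins, model$bank_spec)
  feats <- extract_features(banded, model$bank)
  predict(model$lda, feature_matrix(feats)[, model$mask, drop = FALSE])
}

#' Replay one trial through the online path
#'
#' @param trials An `eeg_trials` object (or a channels x samples matrix).
#' @param model A `bci_model` with frozen offline parameters.
#' @param trial Trial index into `trials` (ignored for a matrix input).
#' @param protocol An [online_protocol()].
#' @return List with `windows` (tibble: `window`, `start_s`, `truth`,
#'   `prediction`, `correct`) and `trigger` (logical: orthosis activation).
#' @export
replay_trial <- function(trials, model, trial = 1,
                         protocol = online_protocol()) {
  x <- if (inherits(trials, "eeg_trials")) trials$data[trial, , ] else as.matrix(trials)
  fs <- model$sampling_rate
  need <- protocol$n_windows * fs
  if (ncol(x) < need) {
    abort(sprintf("trial is %.2f s long; online replay needs %d s",
                  ncol(x) / fs, protocol$n_windows))
  }
  win_data <- array(0, dim = c(protocol$n_windows, nrow(x), fs))
  for (k in seq_len(protocol$n_windows)) {
    win_data[k, , ] <- x[, ((k - 1) * fs + 1):(k * fs)]
  }
  truth <- factor(
    c(rep("REST", protocol$n_rest),
      rep("MI", protocol$n_windows - protocol$n_rest)),
    levels = c("REST", "MI")
  )
  pred <- classify_windows(model, win_data)
  mi_windows <- seq.int(protocol$n_rest + 1, protocol$n_windows)
  trigger <- trigger_decision(pred[mi_windows], protocol$trigger_votes)
  list(
    windows = tibble::tibble(
      window = seq_len(protocol$n_windows),
      start_s = seq_len(protocol$n_windows) - 1,
      truth = truth,
      prediction = pred,
      correct = pred == truth
    ),
    trigger = trigger
  )
}

feedback_band <- function(ct_pct) {
  # 1 = most smiling face (%CT in 100-90), 5 = most serious (< 60)
  ifelse(ct_pct >= 90, 1L,
         ifelse(ct_pct >= 80, 2L,
                ifelse(ct_pct >= 70, 3L,
                       ifelse(ct_pct >= 60, 4L, 5L))))
}

#' Simulate a full online session
#'
#' Replays every trial as six consecutive windows under the frozen model,
#' logs all window-level classification outputs, applies the orthosis
#' trigger rule per trial, and aggregates online %CA (correct windows /
#' total windows), %CT (triggered trials / total trials) and per-run
#' feedback bands.
#'
#' @param trials An `eeg_trials` object (trials in presentation order).
#' @param model A `bci_model`.
#' @param protocol An [online_protocol()].
#' @return A `bci_session` object with `windows` and `trials` tibbles,
#'   `runs` (per-run %CT and feedback band), `ca_pct`, `ct_pct`, and the
#'   mean per-window processing time (informational only).
#' @export
run_session <- function(trials, model, protocol = online_protocol()) {
  stopifnot(inherits(trials, "eeg_trials"), inherits(model, "bci_model"))
  fs <- model$sampling_rate
  nt <- dim(trials$data)[1]
  nch <- dim(trials$data)[2]
  nwpt <- protocol$n_windows
  if (dim(trials$data)[3] < nwpt * fs) {
    abort(sprintf("trials are too short for %d one-second windows", nwpt))
  }

  win_data <- array(0, dim = c(nt * nwpt, nch, fs))
  for (tr in seq_len(nt)) {
    for (k in seq_len(nwpt)) {
      win_data[(tr - 1) * nwpt + k, , ] <-
        trials$data[tr, , ((k - 1) * fs + 1):(k * fs)]
    }
  }
  t0 <- proc.time()[["elapsed"]]
  pred <- classify_windows(model, win_data)
  elapsed <- proc.time()[["elapsed"]] - t0

  truth <- factor(
    rep(c(rep("REST", protocol$n_rest), rep("MI", nwpt - protocol$n_rest)), nt),
    levels = c("REST", "MI")
  )
  run_of <- ceiling(seq_len(nt) / protocol$trials_per_run)
  windows <- tibble::tibble(
    trial = rep(seq_len(nt), each = nwpt),
    run = rep(run_of, each = nwpt),
    window = rep(seq_len(nwpt), nt),
    truth = truth,
    prediction = pred,
    correct = pred == truth
  )
  mi_win <- windows$window > protocol$n_rest
  trial_tbl <- windows |>
    dplyr::filter(mi_win) |>
    dplyr::group_by(.data$trial, .data$run) |>
    dplyr::summarise(
      n_mi_correct = sum(.data$prediction == "MI"),
      trigger = trigger_decision(.data$prediction, protocol$trigger_votes),
      .groups = "drop"
    )
  runs <- trial_tbl |>
    dplyr::group_by(run = .data$run) |>
    dplyr::summarise(ct_pct = 100 * mean(.data$trigger), .groups = "drop") |>
    dplyr::mutate(feedback_band = feedback_band(.data$ct_pct))

  structure(
    list(windows = windows,
         trials = trial_tbl,
         runs = runs,
         ca_pct = 100 * mean(windows$correct),
         ct_pct = 100 * mean(trial_tbl$trigger),
         mean_window_time_s = elapsed / nrow(windows),
         protocol = protocol),
    class = "bci_session"
  )
}

#' @export
print.bci_session <- function(x, ...) {
  cat(sprintf(
    "<bci_session> %d trials: online %%CA %.1f, %%CT %.1f (%d windows)\n",
    nrow(x$trials), x$ca_pct, x$ct_pct, nrow(x$windows)
  ))
  invisible(x)
}

#' Correlate online accuracy with trigger rate across subjects
#'
#' Pearson correlation between per-subject online %CA and %CT, and the r^2
#' of the ordinary least-squares line.
#'
#' @param results Data frame with columns `ca_pct` and `ct_pct` (one row per
#'   subject), or a list of `bci_session` objects.
#' @return A one-row tibble: `r`, `r_squared`, `slope`, `intercept`, `n`.
#' @export
correlate_ca_ct <- function(results) {
  if (!is.data.frame(results)) {
    results <- purrr::map_dfr(results, function(s) {
      tibble::tibble(ca_pct = s$ca_pct, ct_pct = s$ct_pct)
    })
  }
  if (nrow(results) < 3) abort("need at least 3 subjects")
  if (stats::sd(results$ca_pct) == 0 || stats::sd(results$ct_pct) == 0) {
    warn("zero variance in %CA or %CT: correlation undefined")
    return(tibble::tibble(r = NA_real_, r_squared = NA_real_,
                          slope = NA_real_, intercept = NA_real_,
                          n = nrow(results)))
  }
  r <- stats::cor(results$ca_pct, results$ct_pct)
  fit <- stats::lm(ct_pct ~ ca_pct, data = results)
  r_squared <- suppressWarnings(summary(fit)$r.squared)
  tibble::tibble(
    r = r,
    r_squared = r_squared,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n = nrow(results)
  )
}
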