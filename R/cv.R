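# Repeated stratified cross-validation of the full pipeline, with a
# broadband CSP baseline on identical folds. The fold unit is the trial: a
# trial's REST and MI windows always travel together, so sibling windows can
# never straddle the train/test split. Spatial filters, the feature mask and
# the LDA are all refit per fold from the training partition only.

#' Cross-validation scheme
#'
#' @param n_folds Folds per repetition.
#' @param n_repetitions Number of repetitions (fresh fold assignment each).
#' @return A `cv_scheme` object.
#' @export
cv_scheme <- function(n_folds = 10, n_repetitions = 10) {
  if (n_folds < 2 || n_repetitions < 1) abort("invalid cross-validation scheme")
  structure(list(n_folds = n_folds, n_repetitions = n_repetitions),
            class = "cv_scheme")
}

#' Assign trials to folds
#'
#' Random balanced partition: fold sizes differ by at most one trial. Since
#' every trial contributes one window of each class, every fold is exactly
#' class-stratified.
#'
#' @param n_trials Number of trials.
#' @param n_folds Number of folds.
#' @param seed Optional seed (repetition `r` of a run uses `base_seed + r`).
#' @return Integer fold id per trial.
#' @export
make_folds <- function(n_trials, n_folds, seed = NULL) {
  if (n_trials < n_folds) abort("need at least one trial per fold")
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(n_trials)
  fold[sample.int(n_trials)] <- rep_len(seq_len(n_folds), n_trials)
  fold
}

# shared CV engine: `fit_predict(train_idx, test_idx, rep)` returns a row of
# per-fold results
run_cv_engine <- function(n_trials, cv, seed, fit_predict) {
  rows <- list()
  folds_by_rep <- list()
  for (r in seq_len(cv$n_repetitions)) {
    fold <- make_folds(n_trials, cv$n_folds, seed = seed + r)
    folds_by_rep[[r]] <- fold
    for (k in seq_len(cv$n_folds)) {
      test_tr <- which(fold == k)
      train_tr <- which(fold != k)
      rows[[length(rows) + 1]] <- tibble::tibble(
        repetition = r, fold = k,
        !!!fit_predict(train_tr, test_tr, r)
      )
    }
  }
  list(results = dplyr::bind_rows(rows), folds = folds_by_rep)
}

#' Cross-validate the filter-bank CSP + swarm-selection pipeline
#'
#' For every fold of every repetition: CSP filters per subband, the feature
#' mask, and the LDA are fit on the training trials only; the percentage
#' classification accuracy (%CA) is computed on the held-out windows. With
#' the default scheme this yields 100 %CA values.
#'
#' @param trials An `eeg_trials` object.
#' @param windows A [window_spec()].
#' @param bank_spec A [filter_bank_spec()].
#' @param pso A [pso_config()].
#' @param cv A [cv_scheme()].
#' @param seed Integer base seed; repetition `r` derives its folds from
#'   `seed + r` and the swarm consumes the seeded RNG stream.
#' @return A `bci_cv` object: per-fold `results` tibble (`repetition`,
#'   `fold`, `ca_pct`, `n_selected`, `fitness`), per-fold masks, fold
#'   assignments, and summary `mean_ca` / `sd_ca`.
#' @export
run_fbcsp_pso_cv <- function(trials,
                             windows = window_spec(),
                             bank_spec = filter_bank_spec(),
                             pso = pso_config(),
                             cv = cv_scheme(),
                             seed = 1) {
  wins <- extract_windows(trials, windows)
  banded <- apply_filter_bank(wins, bank_spec)
  n_trials <- dim(trials$data)[1]
  if (n_trials < 2 * cv$n_folds) {
    abort("need at least two trials per fold for stratified cross-validation")
  }
  set.seed(seed)
  masks <- list()

  fit_predict <- function(train_tr, test_tr, r) {
    tr_idx <- which(banded$trial %in% train_tr)
    te_idx <- which(banded$trial %in% test_tr)
    bk <- fit_csp_bank(subset_banded(banded, tr_idx))
    Ftr <- extract_features(subset_banded(banded, tr_idx), bk)
    Fte <- extract_features(subset_banded(banded, te_idx), bk)
    sel <- select_features(Ftr, pso)
    model <- lda_train(feature_matrix(Ftr)[, sel$mask, drop = FALSE], Ftr$label)
    pred <- predict(model, feature_matrix(Fte)[, sel$mask, drop = FALSE])
    masks[[length(masks) + 1]] <<- sel$mask
    list(ca_pct = accuracy_pct(pred, Fte$label),
         n_selected = sum(sel$mask),
         fitness = sel$best_fitness)
  }

  eng <- run_cv_engine(n_trials, cv, seed, fit_predict)
  new_bci_cv(eng, method = "fbcsp_pso", n_trials = n_trials,
             masks = masks, seed = seed)
}

#' Cross-validate the broadband CSP baseline
#'
#' Original CSP reference: one 8-32 Hz band-pass (same FIR order), CSP
#' filters, the first and last `m` projection columns (2m = 4 features), and
#' an LDA. Fold assignments are identical to [run_fbcsp_pso_cv()] run with
#' the same `seed` and `cv`, giving a paired comparison.
#'
#' @inheritParams run_fbcsp_pso_cv
#' @param band Broadband pass edges in Hz.
#' @param m Spatial-filter pairs retained from each end of the eigenvalue
#'   spectrum.
#' @param filter_order FIR order for the broadband filter.
#' @return A `bci_cv` object (method `"csp"`).
#' @export
run_csp_baseline_cv <- function(trials,
                                windows = window_spec(),
                                band = c(8, 32),
                                m = 2,
                                filter_order = 30,
                                cv = cv_scheme(),
                                seed = 1) {
  spec <- filter_bank_spec(bands = list(band), filter_order = filter_order)
  wins <- extract_windows(trials, windows)
  banded <- apply_filter_bank(wins, spec)
  n_trials <- dim(trials$data)[1]
  nch <- length(trials$channel_names)
  columns <- c(seq_len(m), seq.int(nch - m + 1, nch))
  set.seed(seed)

  fit_predict <- function(train_tr, test_tr, r) {
    tr_idx <- which(banded$trial %in% train_tr)
    te_idx <- which(banded$trial %in% test_tr)
    bk <- fit_csp_bank(subset_banded(banded, tr_idx))
    Ftr <- extract_features(subset_banded(banded, tr_idx), bk, columns = columns)
    Fte <- extract_features(subset_banded(banded, te_idx), bk, columns = columns)
    model <- lda_train(feature_matrix(Ftr), Ftr$label)
    pred <- predict(model, feature_matrix(Fte))
    list(ca_pct = accuracy_pct(pred, Fte$label),
         n_selected = length(columns),
         fitness = NA_real_)
  }

  eng <- run_cv_engine(n_trials, cv, seed, fit_predict)
  new_bci_cv(eng, method = "csp", n_trials = n_trials, masks = NULL,
             seed = seed)
}

new_bci_cv <- function(eng, method, n_trials, masks, seed) {
  structure(
    list(results = eng$results,
         folds = eng$folds,
         masks = masks,
         method = method,
         n_trials = n_trials,
         mean_ca = mean(eng$results$ca_pct),
         sd_ca = stats::sd(eng$results$ca_pct),
         chance_pct = practical_chance_level(n = 2 * n_trials),
         seed = seed),
    class = "bci_cv"
  )
}

#' @export
print.bci_cv <- function(x, ...) {
  cat(sprintf(
    "<bci_cv> %s: %%CA %.1f +/- %.1f over %d folds (chance %.1f%%)\n",
    x$method, x$mean_ca, x$sd_ca, nrow(x$results), x$chance_pct
  ))
  invisible(x)
}

#' Summarize a subject's offline results
#'
#' Tabulates mean +/- SD %CA per method against the practical level of
#' chance, and (when two methods are supplied) compares their 100 fold-level
#' %CA values with a two-sided Mann-Whitney U test.
#'
#' @param ... Named `bci_cv` objects (e.g. `fbcsp_pso = ..., csp = ...`).
#' @param alpha Significance level for the method comparison.
#' @return A tibble with one row per method (`method`, `mean_ca`, `sd_ca`,
#'   `chance_pct`, `above_chance`); when exactly two methods are given, the
#'   comparison tibble is attached as attribute `"comparison"`.
#' @export
summarize_subject <- function(..., alpha = 0.05) {
  cvs <- list(...)
  if (length(cvs) == 0) abort("supply at least one bci_cv result")
  if (is.null(names(cvs)) || any(names(cvs) == "")) {
    names(cvs) <- vapply(cvs, `[[`, character(1), "method")
  }
  out <- purrr::map2_dfr(cvs, names(cvs), function(cv, nm) {
    tibble::tibble(
      method = nm,
      mean_ca = cv$mean_ca,
      sd_ca = cv$sd_ca,
      chance_pct = cv$chance_pct,
      above_chance = cv$mean_ca > cv$chance_pct
    )
  })
  if (length(cvs) == 2) {
    attr(out, "comparison") <- compare_methods(
      cvs[[1]]$results$ca_pct, cvs[[2]]$results$ca_pct, alpha = alpha
    )
  }
  out
}

#' Fit the deployable model on a full offline session
#'
#' Refits the whole chain once on all trials — per-subband CSP filters, the
#' swarm-selected feature mask, and the LDA — producing the frozen parameter
#' set an online session loads.
#'
#' @inheritParams run_fbcsp_pso_cv
#' @return A `bci_model` object (serializable with [write_bci_model()]).
#' @export
fit_bci_model <- function(trials,
                          windows = window_spec(),
                          bank_spec = filter_bank_spec(),
                          pso = pso_config(),
                          seed = 1) {
  wins <- extract_windows(trials, windows)
  banded <- apply_filter_bank(wins, bank_spec)
  bk <- fit_csp_bank(banded)
  feats <- extract_features(banded, bk)
  set.seed(seed)
  sel <- select_features(feats, pso)
  lda <- lda_train(feature_matrix(feats)[, sel$mask, drop = FALSE], feats$label)
  structure(
    list(bank = bk,
         mask = sel$mask,
         lda = lda,
         layout = sel$layout,
         window_spec = windows,
         bank_spec = bank_spec,
         sampling_rate = trials$sampling_rate,
         channel_names = trials$channel_names,
         selection_history = sel$history),
    class = "bci_model"
  )
}

#' @export
print.bci_model <- function(x, ...) {
  cat(sprintf(
    "<bci_model> %d bands, %d/%d features selected, %d-channel montage\n",
    length(x$bank$W), sum(x$mask), x$layout$D, length(x$channel_names)
  ))
  invisible(x)
}
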