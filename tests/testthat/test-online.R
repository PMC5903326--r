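# online simulator: replay, trigger rule, session bookkeeping

make_small_model <- function(seed = 40) {
  trials <- generate_session(paradigm_spec(n_trials = 16),
                             erd_effect(depth = 0.8), seed = seed)
  fit_bci_model(trials, pso = pso_config(n_particles = 15, n_generations = 10),
                seed = seed)
}

test_that("the orthosis fires exactly for patterns with >= 2 MI votes", {
  patterns <- expand.grid(w1 = c("REST", "MI"), w2 = c("REST", "MI"),
                          w3 = c("REST", "MI"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(patterns))) {
    p <- unlist(patterns[i, ])
    expect_identical(trigger_decision(p), sum(p == "MI") >= 2)
  }
  # flipping any REST vote to MI never un-triggers (monotonicity)
  for (i in seq_len(nrow(patterns))) {
    p <- unlist(patterns[i, ])
    for (j in which(p == "REST")) {
      q <- p; q[j] <- "MI"
      expect_gte(trigger_decision(q), trigger_decision(p))
    }
  }
})

test_that("replaying a trial yields six consecutive windows and a trigger decision", {
  model <- make_small_model()
  trials <- generate_session(paradigm_spec(n_trials = 4),
                             erd_effect(depth = 0.8), seed = 41)
  rt <- replay_trial(trials, model, trial = 2)
  expect_equal(nrow(rt$windows), 6)
  expect_equal(rt$windows$start_s, 0:5)
  expect_equal(as.character(rt$windows$truth),
               c("REST", "REST", "REST", "MI", "MI", "MI"))
  expect_identical(rt$trigger,
                   trigger_decision(rt$windows$prediction[4:6]))

  short <- trials$data[1, , 1:(5 * 256)]
  expect_error(replay_trial(short, model), "6 s")
})

test_that("a session logs every window and aggregates %CA, %CT and run feedback", {
  model <- make_small_model()
  trials <- generate_session(paradigm_spec(n_trials = 20),
                             erd_effect(depth = 0.8), seed = 42)
  s <- run_session(trials, model, online_protocol(trials_per_run = 10))
  expect_equal(nrow(s$windows), 120)
  expect_equal(as.vector(table(s$windows$truth)), c(60, 60))
  expect_equal(s$ca_pct, 100 * mean(s$windows$correct))

  # %CT identity: exactly the fraction of trials with >= 2 of 3 MI windows MI
  per_trial <- tapply(
    s$windows$prediction[s$windows$window > 3] == "MI",
    s$windows$trial[s$windows$window > 3], sum
  )
  expect_equal(s$ct_pct, 100 * mean(per_trial >= 2))
  expect_gte(s$ct_pct, 100 * mean(per_trial == 3))

  expect_equal(nrow(s$runs), 2)
  expect_true(all(s$runs$feedback_band %in% 1:5))
  expect_s3_class(autoplot(s), "ggplot")
  expect_equal(glance(s)$ct_pct, s$ct_pct)
})

test_that("a 120-trial online protocol produces 720 classification outputs, 360 per class", {
  model <- make_small_model()
  trials <- generate_session(paradigm_spec(n_trials = 120),
                             erd_effect(depth = 0.8), seed = 43)
  s <- run_session(trials, model)
  expect_equal(nrow(s$windows), 720)
  expect_equal(as.vector(table(s$windows$truth)), c(360, 360))
  expect_equal(max(s$windows$run), 6) # 20 trials x 3 runs x 2 sessions
})

test_that("an always-MI classifier triggers every trial at 50% window accuracy", {
  model <- make_small_model()
  model$lda$weights[] <- 0
  model$lda$bias <- 1
  trials <- generate_session(paradigm_spec(n_trials = 10),
                             erd_effect(depth = 0.8), seed = 44)
  s <- run_session(trials, model)
  expect_equal(s$ct_pct, 100)
  expect_equal(s$ca_pct, 50)
  expect_equal(s$runs$feedback_band[1], 1L)
})

test_that("replaying the offline analysis windows reproduces offline predictions exactly", {
  model <- make_small_model()
  trials <- generate_session(paradigm_spec(n_trials = 10),
                             erd_effect(depth = 0.8), seed = 45)
  wins <- extract_windows(trials)
  banded <- apply_filter_bank(wins, model$bank_spec)
  feats <- extract_features(banded, model$bank)
  offline_pred <- predict(model$lda,
                          feature_matrix(feats)[, model$mask, drop = FALSE])
  online_pred <- fbcsp:::classify_windows(model, wins$data)
  expect_identical(online_pred, offline_pred)
})

test_that("%CA-%CT correlation reports Pearson r and the matching r-squared", {
  exact <- tibble::tibble(ca_pct = c(60, 70, 80, 90),
                          ct_pct = c(60, 70, 80, 90))
  res <- correlate_ca_ct(exact)
  expect_equal(res$r, 1)
  expect_equal(res$r_squared, 1)

  set.seed(46)
  noisy <- tibble::tibble(ca_pct = rnorm(8, 70, 7))
  noisy$ct_pct <- 0.9 * noisy$ca_pct + rnorm(8, 10, 5)
  res <- correlate_ca_ct(noisy)
  expect_equal(res$r_squared, res$r^2, tolerance = 1e-12)

  anti <- tibble::tibble(ca_pct = c(60, 70, 80), ct_pct = c(90, 75, 50))
  expect_lt(correlate_ca_ct(anti)$r, 0)

  flat <- tibble::tibble(ca_pct = c(70, 70, 70), ct_pct = c(60, 70, 80))
  expect_warning(res <- correlate_ca_ct(flat), "undefined")
  expect_true(is.na(res$r))

  expect_error(correlate_ca_ct(exact[1:2, ]), "3 subjects")
})
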