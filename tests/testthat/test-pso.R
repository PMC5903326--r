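test_that("masks decode by thresholding, never empty, and close under the pairing rule", {
  layout <- feature_layout(6, 11)

  m <- decode_mask(rep(1, 66), layout)
  expect_true(all(m))
  expect_equal(sum(m), 66)

  # all below threshold -> repaired to the highest-position dimension + pair
  pos <- rep(0.49, 66)
  pos[14] <- 0.495 # band 2, filter 3
  m <- decode_mask(pos, layout)
  expect_true(m[14])
  expect_true(m[11 + 9]) # complement: filter 12 - 3 = 9 of band 2
  expect_equal(sum(m), 2)

  # single selected feature drags in its complement
  pos <- rep(0, 66); pos[1] <- 0.7
  m <- decode_mask(pos, layout)
  expect_identical(which(m), c(1L, 11L))
})

test_that("pair closure is the per-band complement map and is idempotent", {
  layout <- feature_layout(6, 11)
  m <- rep(FALSE, 66); m[(4 - 1) * 11 + 6] <- TRUE # band 4, middle filter
  expect_equal(sum(pair_closure(m, layout)), 1) # self-complementary

  set.seed(12)
  for (i in 1:20) {
    m <- runif(66) > 0.7
    closed <- pair_closure(m, layout)
    expect_identical(pair_closure(closed, layout), closed)
    cm <- matrix(closed, 11, 6)
    expect_identical(cm, cm[11:1, , drop = FALSE] | cm)
  }
})

test_that("the fitness is err x 2 + nselec/66 with its documented bounds", {
  layout <- feature_layout(6, 11)
  set.seed(13)
  feats <- noise_features(24, layout, seed = 13)
  # make the table perfectly separable -> err = 0
  sep <- feats
  sep$band_1_filter_1 <- ifelse(sep$label == "MI", 5, -5)
  all_mask <- rep(TRUE, 66)
  expect_equal(as.numeric(pso_fitness(all_mask, sep)), 1.0)

  # evaluating against flipped labels forces err = 1 -> the 3.0 maximum
  flipped <- sep
  flipped$label <- factor(ifelse(sep$label == "MI", "REST", "MI"),
                          levels = c("REST", "MI"))
  expect_equal(as.numeric(pso_fitness(all_mask, sep, eval = flipped)), 3.0)

  # bounds 0 < value <= 3 over random pair-closed masks on pure noise
  f <- pso_fitness(rep(TRUE, 66), feats)
  expect_equal(attr(f, "nselec"), 66)
  vals <- replicate(200, {
    m <- pair_closure(runif(66) > runif(1, 0.3, 0.95), layout)
    if (!any(m)) m[1:2] <- TRUE
    as.numeric(pso_fitness(m, feats))
  })
  expect_true(all(vals > 0 & vals <= 3))
})

test_that("the fast resubstitution fitness equals the reference fitness", {
  layout <- feature_layout(6, 11)
  feats <- noise_features(30, layout, seed = 14)
  fast <- fbcsp:::make_resub_fitness(feats)
  set.seed(15)
  for (i in 1:25) {
    m <- pair_closure(runif(66) > 0.6, layout)
    if (!any(m)) m[c(1, 11)] <- TRUE
    expect_equal(fast(m)$value, as.numeric(pso_fitness(m, feats)),
                 tolerance = 1e-12)
  }
})

test_that("one swarm step reproduces the hand-computed velocity and clamps the position", {
  state <- init_swarm(1, 1)
  state$positions[1, 1] <- 0.5
  state$velocities[1, 1] <- 0.1
  state$pbest_pos[1, 1] <- 0.7
  state$pbest_fit[1] <- 0.1
  state$gbest_pos <- 0.9
  state$gbest_fit <- 0.05
  cfg <- pso_config(n_particles = 1, n_generations = 2, inertia = c(0.5, 0.5))
  # fitness worse than both bests so they stay fixed during the update
  worse <- function(mask) list(value = 10, err = 1)
  out <- step_swarm(state, cfg, worse, feature_layout(1, 1),
                    r1 = matrix(1), r2 = matrix(1))
  # v' = 0.5*0.1 + 1*1*(0.7-0.5) + 1*1*(0.9-0.5) = 0.65; x' = 1.15 -> 1.0
  expect_equal(out$velocities[1, 1], 0.65)
  expect_equal(out$positions[1, 1], 1.0)
})

test_that("a converged swarm is a fixed point and the global best never worsens", {
  layout <- feature_layout(2, 3)
  feats <- noise_features(20, layout, seed = 16)
  fit_fn <- fbcsp:::make_resub_fitness(feats)

  state <- init_swarm(4, layout$D)
  # the whole swarm sits at one point with pbest = gbest = x and v = 0
  state$positions <- matrix(state$positions[1, ], 4, layout$D, byrow = TRUE)
  state$velocities[] <- 0
  state$pbest_pos <- state$positions
  state$pbest_fit[] <- -1 # already better than anything achievable
  state$gbest_pos <- state$positions[1, ]
  state$gbest_fit <- -1
  cfg <- pso_config(n_particles = 4, n_generations = 3)
  out <- step_swarm(state, cfg, fit_fn, layout)
  expect_equal(out$positions, state$positions)

  set.seed(17)
  sel <- select_features(feats, pso_config(n_particles = 10, n_generations = 15),
                         layout)
  expect_true(all(diff(sel$history$best_fitness) <= 0))
})

test_that("a single separating feature triggers the zero-error early stop with a small mask", {
  layout <- feature_layout(6, 11)
  feats <- noise_features(40, layout, seed = 18)
  feats$band_1_filter_7 <- ifelse(feats$label == "MI", 3, -3)
  sel <- select_features(feats, pso_config(), layout, seed = 19)
  expect_equal(sel$best_err, 0)
  expect_lt(nrow(sel$history), 50) # stopped before the generation budget
  # stopping at the first zero-error particle leaves no time to prune, so
  # the mask is only required to be a strict, pair-closed subset
  expect_lt(sum(sel$mask), 66)
  expect_identical(sel$mask, pair_closure(sel$mask, layout))
})

test_that("selection is reproducible under a fixed seed", {
  layout <- feature_layout(3, 4)
  feats <- noise_features(24, layout, seed = 20)
  cfg <- pso_config(n_particles = 12, n_generations = 10)
  a <- select_features(feats, cfg, layout, seed = 21)
  b <- select_features(feats, cfg, layout, seed = 21)
  expect_identical(a$mask, b$mask)
  expect_identical(a$history, b$history)
})

test_that("the swarm matches the exhaustive pair-closed optimum on a 6-feature toy", {
  layout <- feature_layout(6, 1) # pairing trivial: 63 candidate subsets
  hits <- 0
  for (seed in 1:5) {
    feats <- noise_features(40, layout, seed = 100 + seed)
    feats$band_1_filter_1 <- feats$band_1_filter_1 +
      ifelse(feats$label == "MI", 1.2, -1.2)
    feats$band_4_filter_1 <- feats$band_4_filter_1 +
      ifelse(feats$label == "MI", 0.8, -0.8)
    best_exh <- exhaustive_best_fitness(feats, layout)
    sel <- select_features(feats, pso_config(), layout, seed = seed)
    if (abs(sel$best_fitness - best_exh) < 1e-12) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("pure-noise tables drive the selected-feature count down", {
  # needs enough rows that resubstitution error cannot reach zero, otherwise
  # the zero-error stop fires before the size penalty can act
  layout <- feature_layout(6, 11)
  ns <- vapply(1:3, function(s) {
    feats <- noise_features(400, layout, seed = 200 + s)
    sel <- select_features(feats, pso_config(), layout, seed = s)
    sum(sel$mask)
  }, numeric(1))
  expect_lt(stats::median(ns), 33)
})
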