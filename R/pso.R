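# Particle swarm feature selection.
#
# Particles live in [0, 1]^D; a position decodes to a feature mask by
# thresholding at 0.5, then closing the mask under the CSP pairing rule
# (within each band, filter j pairs with filter nf + 1 - j). The fitness of a
# mask is err * 2 + nselec / D, where err is the resubstitution error of an
# LDA trained on the masked training features — the swarm minimizes
# classification error first and feature count second.

#' Feature-table layout
#'
#' Records how feature columns are organised (band-major) so the pairing rule
#' knows each filter's complement.
#'
#' @param n_bands Number of subbands.
#' @param n_filters Spatial filters per band.
#' @return A `feature_layout` object; `n_bands * n_filters` is the search
#'   space dimension D.
#' @export
feature_layout <- function(n_bands = 6, n_filters = 11) {
  structure(list(n_bands = n_bands, n_filters = n_filters,
                 D = n_bands * n_filters),
            class = "feature_layout")
}

#' Swarm configuration
#'
#' @param n_particles,n_generations Swarm size and generation budget.
#' @param c1,c2 Cognitive and social acceleration constants.
#' @param inertia Length-2: inertia weight at the first and last generation
#'   (linear schedule; the default descends 1 to 0,
#'   exploration to exploitation).
#' @param v_max Velocity magnitude clamp.
#' @param threshold Position threshold at or above which a feature is
#'   selected.
#' @param err_weight Weight of the classification error in the fitness.
#' @return A `pso_config` object.
#' @export
pso_config <- function(n_particles = 50, n_generations = 50,
                       c1 = 1, c2 = 1,
                       inertia = c(1, 0),
                       v_max = 1,
                       threshold = 0.5,
                       err_weight = 2) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  if (v_max <= 0 || n_particles < 1 || n_generations < 1) {
    abort("swarm bounds must be positive")
  }
  structure(
    list(n_particles = n_particles, n_generations = n_generations,
         c1 = c1, c2 = c2, inertia = inertia, v_max = v_max,
         threshold = threshold, err_weight = err_weight),
    class = "pso_config"
  )
}

#' Close a feature mask under the CSP pairing rule
#'
#' CSP features come in eigenvalue-complementary pairs: within each band,
#' filter `j` (sorted by descending eigenvalue) pairs with filter
#' `nf + 1 - j`. Selecting one member selects the other; the middle filter of
#' an odd-sized band is its own complement. Idempotent.
#'
#' @param mask Logical vector of length `layout$D`, band-major.
#' @param layout A [feature_layout()].
#' @return Pair-closed logical mask.
#' @export
#' @examples
#' m <- rep(FALSE, 66); m[1] <- TRUE
#' which(pair_closure(m, feature_layout()))
pair_closure <- function(mask, layout = feature_layout()) {
  stopifnot(length(mask) == layout$D)
  m <- matrix(mask, nrow = layout$n_filters, ncol = layout$n_bands)
  as.vector(m | m[rev(seq_len(layout$n_filters)), , drop = FALSE])
}

#' Decode a particle position into a feature mask
#'
#' Features whose position value is at or above `threshold` are selected,
#' then the mask is closed under the pairing rule. An all-below-threshold
#' position is repaired by forcing on the dimension with the highest value
#' (so a mask is never empty).
#'
#' @param position Numeric vector in `[0, 1]` of length `layout$D`.
#' @param layout A [feature_layout()].
#' @param threshold Selection threshold.
#' @return Logical feature mask.
#' @export
decode_mask <- function(position, layout = feature_layout(), threshold = 0.5) {
  raw <- position >= threshold
  if (!any(raw)) raw[which.max(position)] <- TRUE
  pair_closure(raw, layout)
}

#' Multi-objective feature-subset fitness
#'
#' `value = err_weight * err + nselec / D`, where `err` is the classification
#' error of an LDA trained on the masked training features and evaluated on
#' `eval` (by default the training set itself, i.e. resubstitution error) and
#' `nselec` the number of selected features. Bounded by `0 < value <= 3` at
#' the default weight.
#'
#' @param mask Logical feature mask (pair-closed, non-empty).
#' @param train Feature tibble used to fit the LDA.
#' @param eval Feature tibble on which the error is computed (default:
#'   `train`).
#' @param err_weight Error weight (default 2).
#' @return Fitness value with attributes `err` and `nselec`.
#' @export
pso_fitness <- function(mask, train, eval = train, err_weight = 2) {
  if (!any(mask)) abort("mask must select at least one feature")
  Xtr <- feature_matrix(train)[, mask, drop = FALSE]
  Xev <- feature_matrix(eval)[, mask, drop = FALSE]
  fit <- lda_train(Xtr, train$label)
  err <- 1 - accuracy_pct(predict(fit, Xev), eval$label) / 100
  structure(err_weight * err + sum(mask) / length(mask),
            err = err, nselec = sum(mask))
}

# fast resubstitution fitness: precompute the full pooled covariance and
# class means once; a mask then costs one submatrix solve. Exactly the
# pso_fitness() math (a pooled covariance submatrix is the pooled covariance
# of the masked features).
make_resub_fitness <- function(train, err_weight = 2) {
  X <- feature_matrix(train)
  y <- train$label
  is_mi <- y == "MI"
  n0 <- sum(!is_mi); n1 <- sum(is_mi)
  mu0 <- colMeans(X[!is_mi, , drop = FALSE])
  mu1 <- colMeans(X[is_mi, , drop = FALSE])
  Sp <- ((n0 - 1) * stats::cov(X[!is_mi, , drop = FALSE]) +
           (n1 - 1) * stats::cov(X[is_mi, , drop = FALSE])) / (n0 + n1 - 2)
  D <- ncol(X)
  function(mask) {
    idx <- which(mask)
    sol <- solve_pooled(Sp[idx, idx, drop = FALSE], (mu1 - mu0)[idx])
    w <- sol$x
    b <- -sum(w * ((mu0 + mu1) / 2)[idx])
    score <- drop(X[, idx, drop = FALSE] %*% w) + b
    err <- mean((score > 0) != is_mi)
    list(value = err_weight * err + length(idx) / D, err = err)
  }
}

#' Initialize a particle swarm
#'
#' Positions uniform in `[0, 1]`; velocities uniform in `[-0.1, 0.1]`.
#'
#' @param n_particles Swarm size.
#' @param D Search-space dimension.
#' @return A `swarm_state` object.
#' @export
init_swarm <- function(n_particles, D) {
  structure(
    list(
      positions = matrix(runif(n_particles * D), n_particles, D),
      velocities = matrix(runif(n_particles * D, -1, 1) * 0.1, n_particles, D),
      pbest_pos = matrix(NA_real_, n_particles, D),
      pbest_fit = rep(Inf, n_particles),
      gbest_pos = rep(NA_real_, D),
      gbest_fit = Inf,
      gbest_err = Inf,
      generation = 0L
    ),
    class = "swarm_state"
  )
}

#' Advance the swarm by one generation
#'
#' Evaluates every particle at its current position, updates personal and
#' global bests (only when strictly better; ties keep the first-found best),
#' then applies the velocity/position update
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`; `x <- x + v`,
#' with `|v|` clamped to `v_max` and positions clamped to `[0, 1]`.
#' `r1`, `r2` are drawn per particle and per dimension.
#'
#' @param state A `swarm_state`.
#' @param config A [pso_config()].
#' @param fitness_fn Function taking a logical mask, returning a list with
#'   `value` and `err` (see [make_resub_fitness()]).
#' @param layout A [feature_layout()] for mask decoding.
#' @param r1,r2 Optional fixed random matrices (particles x D), for
#'   deterministic stepping; default: fresh uniform draws.
#' @return The updated `swarm_state`.
#' @export
step_swarm <- function(state, config, fitness_fn,
                       layout = feature_layout(), r1 = NULL, r2 = NULL) {
  np <- nrow(state$positions)
  D <- ncol(state$positions)
  gen <- state$generation + 1L

  for (i in seq_len(np)) {
    mask <- decode_mask(state$positions[i, ], layout, config$threshold)
    f <- fitness_fn(mask)
    if (f$value < state$pbest_fit[i]) {
      state$pbest_fit[i] <- f$value
      state$pbest_pos[i, ] <- state$positions[i, ]
    }
    if (f$value < state$gbest_fit) {
      state$gbest_fit <- f$value
      state$gbest_err <- f$err
      state$gbest_pos <- state$positions[i, ]
    }
  }

  G <- config$n_generations
  w_inertia <- if (G > 1) {
    config$inertia[1] + (config$inertia[2] - config$inertia[1]) * (gen - 1) / (G - 1)
  } else {
    config$inertia[1]
  }
  r1 <- r1 %||% matrix(runif(np * D), np, D)
  r2 <- r2 %||% matrix(runif(np * D), np, D)
  v <- w_inertia * state$velocities +
    config$c1 * r1 * (state$pbest_pos - state$positions) +
    config$c2 * r2 * (sweep(-state$positions, 2, state$gbest_pos, `+`))
  v <- pmin(pmax(v, -config$v_max), config$v_max)
  x <- pmin(pmax(state$positions + v, 0), 1)

  state$velocities <- v
  state$positions <- x
  state$generation <- gen
  state
}

#' Select a feature subset with particle swarm optimisation
#'
#' Runs up to `config$n_generations` generations of `config$n_particles`
#' particles, minimizing [pso_fitness()] under resubstitution error, and
#' stops early as soon as the global best reaches zero classification error.
#'
#' @param train Feature tibble (from [extract_features()]) with both classes.
#' @param config A [pso_config()].
#' @param layout A [feature_layout()]; default taken from `train`.
#' @param seed Optional integer seed for a self-contained reproducible run;
#'   default uses the current RNG stream.
#' @return A `pso_selection` object: the pair-closed global-best `mask`, the
#'   per-generation `history` tibble (`generation`, `best_fitness`,
#'   `best_err`, `best_nselec`), and the best position.
#' @export
select_features <- function(train, config = pso_config(),
                            layout = NULL, seed = NULL) {
  layout <- layout %||% attr(train, "layout") %||% feature_layout()
  if (nlevels(droplevels(train$label)) < 2) {
    abort("training features must contain both classes")
  }
  if (!is.null(seed)) set.seed(seed)
  fitness_fn <- make_resub_fitness(train, config$err_weight)
  state <- init_swarm(config$n_particles, layout$D)
  hist <- vector("list", config$n_generations)
  for (gen in seq_len(config$n_generations)) {
    state <- step_swarm(state, config, fitness_fn, layout)
    mask_now <- decode_mask(state$gbest_pos, layout, config$threshold)
    hist[[gen]] <- tibble::tibble(
      generation = gen,
      best_fitness = state$gbest_fit,
      best_err = state$gbest_err,
      best_nselec = sum(mask_now)
    )
    if (state$gbest_err == 0) break
  }
  mask <- decode_mask(state$gbest_pos, layout, config$threshold)
  structure(
    list(mask = mask,
         history = dplyr::bind_rows(hist),
         best_fitness = state$gbest_fit,
         best_err = state$gbest_err,
         best_position = state$gbest_pos,
         layout = layout,
         config = config),
    class = "pso_selection"
  )
}

#' @export
print.pso_selection <- function(x, ...) {
  cat(sprintf(
    "<pso_selection> %d/%d features, fitness %.4f (err %.3f) after %d generations\n",
    sum(x$mask), x$layout$D, x$best_fitness, x$best_err, nrow(x$history)
  ))
  invisible(x)
}
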