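test_that("class covariances are trace-normalized averages with analytic structure", {
  set.seed(3)
  # identical signals for both classes -> identical covariances
  sig <- matrix(rnorm(2 * 64), 2)
  b_same <- manual_banded(list(sig, sig, sig, sig),
                          c("REST", "MI", "REST", "MI"))
  S <- estimate_class_covariances(b_same, 1)
  expect_equal(S$S1, S$S2, tolerance = 1e-12)
  expect_equal(sum(diag(S$S1)), 1, tolerance = 1e-12)

  # class 1: source on channel 1 only; class 2: the reverse
  src <- function(on) {
    m <- matrix(0, 2, 64)
    m[on, ] <- rnorm(64)
    m
  }
  b_axis <- manual_banded(list(src(1), src(1), src(2), src(2)),
                          c("MI", "MI", "REST", "REST"))
  S <- estimate_class_covariances(b_axis, 1)
  expect_equal(S$S1, diag(c(1, 0)), tolerance = 1e-10)
  expect_equal(S$S2, diag(c(0, 1)), tolerance = 1e-10)

  one_class <- manual_banded(list(sig, sig), c("MI", "MI"))
  expect_error(estimate_class_covariances(one_class, 1), "class")
})

test_that("spatial filters solve the generalized eigenproblem", {
  # symmetric classes: every eigenvalue 1/2
  f <- compute_spatial_filters(diag(3), diag(3))
  expect_equal(f$eigenvalues, rep(0.5, 3), tolerance = 1e-12)

  # 2x2 analytic case
  f <- compute_spatial_filters(diag(c(3, 1)), diag(c(1, 3)))
  expect_equal(f$eigenvalues, c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(abs(f$W) / max(abs(f$W)), diag(2), tolerance = 1e-10)

  expect_error(compute_spatial_filters(matrix(c(1, 2, 0, 1), 2), diag(2)),
               "symmetric")

  # defining-equation residual on random SPD pairs
  set.seed(11)
  for (rep in 1:20) {
    S1 <- rspd(11); S2 <- rspd(11)
    f <- compute_spatial_filters(S1, S2)
    C <- S1 + S2
    for (j in 1:11) {
      res <- S1 %*% f$W[, j] - f$eigenvalues[j] * C %*% f$W[, j]
      expect_lt(sqrt(sum(res^2)), 1e-8)
    }
    expect_true(all(diff(f$eigenvalues) <= 1e-12))
    expect_true(all(f$eigenvalues > -1e-10 & f$eigenvalues < 1 + 1e-10))
    # W' (S1 + S2) W diagonal (identity, by the whitening construction)
    expect_equal(t(f$W) %*% C %*% f$W, diag(11), tolerance = 1e-8)
  }
})

test_that("features are 66 band-major log variance ratios that sum to one per band", {
  bank <- fit_csp_bank(tiny_banded)
  feats <- extract_features(tiny_banded, bank)
  fm <- feature_matrix(feats)
  expect_equal(ncol(fm), 66)
  expect_equal(colnames(fm)[1:12],
               c(sprintf("band_1_filter_%d", 1:11), "band_2_filter_1"))
  expect_true(all(is.finite(fm)))
  for (b in 1:6) {
    block <- fm[, (b - 1) * 11 + 1:11]
    expect_equal(rowSums(exp(block)), rep(1, nrow(fm)), tolerance = 1e-10)
  }
})

test_that("features are invariant to global scaling and to filter sign flips", {
  bank <- fit_csp_bank(tiny_banded)
  feats <- extract_features(tiny_banded, bank)

  scaled <- tiny_banded
  scaled$data <- scaled$data * 7.3
  expect_equal(feature_matrix(extract_features(scaled, bank)),
               feature_matrix(feats), tolerance = 1e-10)

  flipped <- bank
  flipped$W <- lapply(bank$W, function(W) { W[, 3] <- -W[, 3]; W })
  expect_equal(feature_matrix(extract_features(tiny_banded, flipped)),
               feature_matrix(feats), tolerance = 1e-12)
})

test_that("the toy problem's discriminative filter dominates its own class's features", {
  set.seed(5)
  src <- function(on) {
    m <- matrix(0, 2, 64)
    m[on, ] <- rnorm(64)
    m[-on, ] <- 0.05 * rnorm(64)
    m
  }
  train <- manual_banded(
    c(lapply(1:4, function(i) src(1)), lapply(1:4, function(i) src(2))),
    rep(c("MI", "REST"), each = 4)
  )
  S <- estimate_class_covariances(train, 1)
  f <- compute_spatial_filters(S$S1, S$S2)
  bank <- structure(
    list(W = list(f$W), eigenvalues = list(f$eigenvalues),
         band_edges = matrix(c(8, 12), 1), channel_names = c("ch1", "ch2")),
    class = "csp_bank"
  )
  test_mi <- manual_banded(list(src(1), src(1)), c("MI", "MI"))
  fm <- feature_matrix(extract_features(test_mi, bank))
  # filter 1 has the largest MI eigenvalue -> largest variance share on MI data
  expect_true(all(fm[, 1] > fm[, 2]))
})

test_that("on training data the mean trace-normalized projection variance approximates the eigenvalue", {
  bank <- fit_csp_bank(tiny_banded)
  b <- 1
  mi_idx <- which(tiny_banded$label == "MI")
  W <- bank$W[[b]]
  lam <- bank$eigenvalues[[b]]
  v <- sapply(mi_idx, function(i) {
    X <- tiny_banded$data[i, b, , ]
    proj <- crossprod(W, X)
    rowSums(proj^2) / sum(X^2)
  })
  expect_equal(rowMeans(v), lam, tolerance = 0.05)
})
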