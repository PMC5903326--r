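# Shared fixtures, built in code at load time.

# small ERD-bearing session reused by several files (12 trials is enough for
# window/feature shape checks and quick end-to-end fits)
tiny_trials <- generate_session(
  paradigm_spec(n_trials = 12), erd_effect(depth = 0.7), seed = 42
)
tiny_windows <- extract_windows(tiny_trials)
tiny_banded <- apply_filter_bank(tiny_windows)

# random symmetric positive definite matrix
rspd <- function(n) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) + diag(n) * 0.1
}

# mean band power of a signal segment via the raw periodogram — the
# independent PSD oracle used against the generator
periodogram_band_power <- function(x, fs, band) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n
  fr <- (seq_len(n) - 1) * fs / n
  mean(P[fr >= band[1] & fr <= band[2]])
}

# hand-built banded-window object: `windows` is a list of channels x samples
# matrices, one per window
manual_banded <- function(windows, labels, fs = 64) {
  nw <- length(windows)
  nch <- nrow(windows[[1]])
  ns <- ncol(windows[[1]])
  data <- array(0, dim = c(nw, 1, nch, ns))
  for (i in seq_len(nw)) data[i, 1, , ] <- windows[[i]]
  structure(
    list(data = data,
         label = factor(labels, levels = c("REST", "MI")),
         trial = seq_len(nw),
         band_edges = matrix(c(8, 12), 1),
         sampling_rate = fs,
         channel_names = paste0("ch", seq_len(nch))),
    class = "eeg_banded"
  )
}

# feature tibble with D pure-noise columns under a given layout
noise_features <- function(n, layout, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * layout$D), n)
  colnames(X) <- as.vector(vapply(
    seq_len(layout$n_bands),
    function(b) sprintf("band_%d_filter_%d", b, seq_len(layout$n_filters)),
    character(layout$n_filters)
  ))
  out <- tibble::as_tibble(as.data.frame(X))
  out <- tibble::add_column(
    out,
    trial = seq_len(n),
    label = factor(rep(c("REST", "MI"), length.out = n), levels = c("REST", "MI")),
    .before = 1
  )
  attr(out, "layout") <- layout
  out
}

# exhaustive pair-closed-subset optimum of the resubstitution fitness
exhaustive_best_fitness <- function(features, layout, err_weight = 2) {
  D <- layout$D
  best <- Inf
  for (code in seq_len(2^D - 1)) {
    mask <- as.logical(bitwAnd(code, 2^(seq_len(D) - 1)))
    if (!identical(mask, pair_closure(mask, layout))) next
    v <- as.numeric(pso_fitness(mask, features, err_weight = err_weight))
    if (v < best) best <- v
  }
  best
}
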