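# Analysis-window extraction and the temporal filter bank.

#' Analysis-window specification
#'
#' One-second windows cut from each trial: the REST window from the rest
#' interval and the MI window from the motor-imagery interval. Times are
#' 0-based seconds from trial onset; windows are half-open `[start, end)` in
#' samples.
#'
#' @param rest_window,mi_window Numeric length-2 `(start, end)` in seconds.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(rest_window = c(1.5, 2.5),
                        mi_window = c(3.5, 4.5)) {
  for (w in list(rest_window, mi_window)) {
    if (length(w) != 2 || abs((w[2] - w[1]) - 1) > 1e-9) {
      abort("analysis windows must be exactly 1 s long")
    }
  }
  structure(list(rest_window = rest_window, mi_window = mi_window),
            class = "window_spec")
}

#' Filter-bank specification
#'
#' Six contiguous 4-Hz subbands spanning the mu and beta range, plus a 60 Hz
#' band-stop notch, all even-order linear-phase FIRs.
#'
#' @param bands List of `(low, high)` band edges in Hz, ordered.
#' @param filter_order Even FIR order (31 taps at the default 30).
#' @param notch Logical: apply the band-stop notch before the bank.
#' @param notch_band Notch stopband edges in Hz.
#' @param transition Design transition bandwidth in Hz for the subbands.
#' @param trim_transient Logical: drop the first `filter_order + 1` output
#'   samples of each window (variance features are robust to the transient,
#'   so the default keeps full windows).
#' @return An object of class `filter_bank_spec`.
#' @export
filter_bank_spec <- function(bands = list(c(8, 12), c(12, 16), c(16, 20),
                                          c(20, 24), c(24, 28), c(28, 32)),
                             filter_order = 30,
                             notch = TRUE,
                             notch_band = c(59, 61),
                             transition = 8,
                             trim_transient = FALSE) {
  if (filter_order %% 2 != 0) abort("filter_order must be even")
  lows <- vapply(bands, `[`, numeric(1), 1)
  highs <- vapply(bands, `[`, numeric(1), 2)
  if (any(highs <= lows) || any(lows <= 0)) abort("invalid band edges")
  if (is.unsorted(lows)) abort("bands must be ordered by lower edge")
  structure(
    list(bands = bands, filter_order = filter_order, notch = notch,
         notch_band = notch_band, transition = transition,
         trim_transient = trim_transient),
    class = "filter_bank_spec"
  )
}

#' Extract labelled 1-s analysis windows from trials
#'
#' Cuts, from every trial, one REST window and one MI window at the times in
#' `spec`. Window rows are ordered trial-major (trial 1 REST, trial 1 MI,
#' trial 2 REST, ...).
#'
#' @param trials An `eeg_trials` object.
#' @param spec A [window_spec()].
#' @return An `eeg_windows` object: `data` (windows x channels x samples),
#'   `label` (factor REST/MI), `trial` (source trial index).
#' @export
extract_windows <- function(trials, spec = window_spec()) {
  stopifnot(inherits(trials, "eeg_trials"))
  fs <- trials$sampling_rate
  n_samp <- dim(trials$data)[3]
  n_trials <- dim(trials$data)[1]
  nch <- dim(trials$data)[2]

  idx_of <- function(w, what) {
    i0 <- round(w[1] * fs)
    i1 <- round(w[2] * fs)
    if (i0 < 0 || i1 > n_samp) {
      abort(sprintf(
        "%s window [%g, %g) s lies outside trial 1..%d (duration %g s)",
        what, w[1], w[2], n_trials, n_samp / fs
      ))
    }
    seq.int(i0 + 1, i1)
  }
  rest_idx <- idx_of(spec$rest_window, "REST")
  mi_idx <- idx_of(spec$mi_window, "MI")

  nw <- 2 * n_trials
  data <- array(0, dim = c(nw, nch, fs))
  data[seq(1, nw, by = 2), , ] <- trials$data[, , rest_idx, drop = FALSE]
  data[seq(2, nw, by = 2), , ] <- trials$data[, , mi_idx, drop = FALSE]

  structure(
    list(data = data,
         label = factor(rep(c("REST", "MI"), n_trials),
                        levels = c("REST", "MI")),
         trial = rep(seq_len(n_trials), each = 2),
         sampling_rate = fs,
         channel_names = trials$channel_names),
    class = "eeg_windows"
  )
}

# wrap a raw window array (windows x channels x samples) with labels
as_eeg_windows <- function(data, label, trial, fs, channel_names) {
  structure(
    list(data = data, label = label, trial = trial, sampling_rate = fs,
         channel_names = channel_names),
    class = "eeg_windows"
  )
}

fb_filters <- function(spec, fs) {
  lapply(spec$bands, function(bd) {
    design_fir_bandpass(bd[1], bd[2], fs, order = spec$filter_order,
                        transition = spec$transition)
  })
}

#' Decompose windows into filter-bank subbands
#'
#' Applies the (optional) 60 Hz notch followed by each band-pass of the bank,
#' causally and independently per window, exactly as an online system filters
#' each 1-s window as it elapses.
#'
#' @param windows An `eeg_windows` object.
#' @param spec A [filter_bank_spec()].
#' @return An `eeg_banded` object with `data` array
#'   windows x bands x channels x samples and `band_edges`.
#' @export
apply_filter_bank <- function(windows, spec = filter_bank_spec()) {
  stopifnot(inherits(windows, "eeg_windows"))
  fs <- windows$sampling_rate
  d <- dim(windows$data)
  nw <- d[1]; nch <- d[2]; ns <- d[3]
  if (ns < 3 * (spec$filter_order + 1)) {
    warn(sprintf(
      "windows of %d samples are shorter than 3x the filter length (%d); edge effects dominate",
      ns, spec$filter_order + 1
    ))
  }
  # samples x (channel, window) matrix: each column one signal
  X <- matrix(aperm(windows$data, c(3, 2, 1)), nrow = ns)
  if (isTRUE(spec$notch)) {
    bstop <- design_fir_bandstop(spec$notch_band[1], spec$notch_band[2], fs,
                                 order = spec$filter_order)
    X <- fir_filter_mat(bstop, X)
  }
  coefs <- fb_filters(spec, fs)
  nb <- length(coefs)
  keep <- if (isTRUE(spec$trim_transient)) {
    seq.int(spec$filter_order + 2, ns)
  } else {
    seq_len(ns)
  }
  out <- array(0, dim = c(nw, nb, nch, length(keep)))
  for (b in seq_len(nb)) {
    Y <- fir_filter_mat(coefs[[b]], X)[keep, , drop = FALSE]
    out[, b, , ] <- aperm(array(Y, dim = c(length(keep), nch, nw)), c(3, 2, 1))
  }
  structure(
    list(data = out, label = windows$label, trial = windows$trial,
         band_edges = do.call(rbind, spec$bands),
         sampling_rate = fs, channel_names = windows$channel_names,
         spec = spec),
    class = "eeg_banded"
  )
}

subset_banded <- function(banded, idx) {
  banded$data <- banded$data[idx, , , , drop = FALSE]
  banded$label <- banded$label[idx]
  banded$trial <- banded$trial[idx]
  banded
}
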