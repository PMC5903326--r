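# Synthetic Graz-paradigm EEG with a controllable ERD.
#
# Each channel is 1/f noise + band-limited oscillators + an optional line
# sinusoid. The ERD is applied by splitting the composite signal into its
# target-band component (brick-wall FFT split over the whole trial) and
# scaling that component by sqrt(1 - depth) from the effect onset onwards,
# so in-band MI power is (1 - depth) times in-band rest power by construction.

# zero-phase brick-wall band component of a single signal
band_component <- function(x, band, fs) {
  n <- length(x)
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- (freqs >= band[1] & freqs <= band[2]) |
    (freqs >= fs - band[2] & freqs <= fs - band[1])
  Re(fft(fft(x) * keep, inverse = TRUE)) / n
}

pink_noise <- function(n, fs, sd_target, exponent) {
  w <- rnorm(n)
  freqs <- (seq_len(n) - 1) * fs / n
  f_fold <- pmin(freqs, fs - freqs) # two-sided spectrum
  scale <- ifelse(f_fold > 0, 1 / f_fold^(exponent / 2), 0)
  x <- Re(fft(fft(w) * scale, inverse = TRUE)) / n
  x / stats::sd(x) * sd_target
}

band_noise <- function(n, fs, band, sd_target) {
  x <- band_component(rnorm(n), band, fs)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * sd_target
}

#' Generate a synthetic motor-imagery EEG session
#'
#' Produces a seeded, fully reproducible session of Graz-paradigm trials with
#' a controllable event-related desynchronization: at the `effect` channels,
#' band-limited power during the MI segment equals `(1 - depth)` times the
#' rest-segment band power, in expectation.
#'
#' @param spec A [paradigm_spec()].
#' @param effect An [erd_effect()] (or `NULL` for a null session).
#' @param noise A [noise_spec()].
#' @param seed Integer seed; the session is a deterministic function of
#'   `(spec, effect, noise, seed)`.
#'
#' @return An `eeg_trials` object: list with `data` (array trials x channels
#'   x samples, microvolts), `sampling_rate`, `channel_names`, `paradigm`.
#' @export
#' @examples
#' tr <- generate_session(paradigm_spec(n_trials = 4), seed = 1)
#' dim(tr$data)
generate_session <- function(spec = paradigm_spec(),
                             effect = erd_effect(),
                             noise = noise_spec(),
                             seed = 1) {
  stopifnot(inherits(spec, "paradigm_spec"))
  fs <- spec$sampling_rate
  nyq <- fs / 2
  if (!is.null(effect)) {
    stopifnot(inherits(effect, "erd_effect"))
    if (effect$band[2] >= nyq) {
      abort(sprintf("ERD band upper edge (%g Hz) must be below Nyquist (%g Hz)",
                    effect$band[2], nyq))
    }
    missing_ch <- setdiff(effect$channels, spec$channels)
    if (length(missing_ch)) {
      abort(paste0("ERD target channels not in montage: ",
                   paste(missing_ch, collapse = ", ")))
    }
  }
  for (osc in noise$oscillations) {
    if (osc$band[2] >= nyq) abort("oscillator band must be below Nyquist")
  }

  set.seed(seed)
  n <- spec$n_samples
  nch <- length(spec$channels)
  tvec <- (seq_len(n) - 1) / fs
  data <- array(0, dim = c(spec$n_trials, nch, n))

  # multiplicative amplitude envelope implementing the ERD: ramps down over
  # 0.1 s so the effect is fully established at rest_duration + onset_latency
  envelope <- NULL
  if (!is.null(effect) && effect$depth > 0) {
    onset_t <- spec$rest_duration + effect$onset_latency
    ramp <- 0.1
    g_low <- sqrt(1 - effect$depth)
    envelope <- ifelse(
      tvec < onset_t - ramp, 1,
      ifelse(tvec >= onset_t, g_low,
             g_low + (1 - g_low) * (1 + cos(pi * (tvec - (onset_t - ramp)) / ramp)) / 2)
    )
  }

  for (tr in seq_len(spec$n_trials)) {
    for (ch in seq_len(nch)) {
      x <- pink_noise(n, fs, noise$pink_sd, noise$pink_exponent)
      for (osc in noise$oscillations) {
        osc_ch <- osc$channels %||% spec$channels
        if (spec$channels[ch] %in% osc_ch) {
          x <- x + band_noise(n, fs, osc$band, osc$sd)
        }
      }
      if (!is.null(noise$line_freq) && noise$line_amplitude > 0) {
        x <- x + noise$line_amplitude *
          sin(2 * pi * noise$line_freq * tvec + runif(1, 0, 2 * pi))
      }
      if (!is.null(envelope) && spec$channels[ch] %in% effect$channels) {
        b <- band_component(x, effect$band, fs)
        x <- x - b + b * envelope
      }
      data[tr, ch, ] <- x
    }
  }

  structure(
    list(data = data, sampling_rate = fs, channel_names = spec$channels,
         paradigm = spec, effect = effect, noise = noise, seed = seed),
    class = "eeg_trials"
  )
}

#' @export
print.eeg_trials <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_trials> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sampling_rate))
  invisible(x)
}

#' Construct an `eeg_trials` object from an array
#'
#' @param data Numeric array trials x channels x samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_names Channel labels matching `dim(data)[2]`.
#' @param paradigm Optional [paradigm_spec()].
#' @return An `eeg_trials` object.
#' @export
as_eeg_trials <- function(data, sampling_rate, channel_names,
                          paradigm = NULL) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[2] == length(channel_names))
  if (anyNA(data) || any(!is.finite(data))) {
    abort("trial data must be finite (no NA/Inf)")
  }
  structure(
    list(data = data, sampling_rate = sampling_rate,
         channel_names = channel_names, paradigm = paradigm),
    class = "eeg_trials"
  )
}

# subset trials, keeping metadata
subset_trials <- function(trials, idx) {
  trials$data <- trials$data[idx, , , drop = FALSE]
  trials
}
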