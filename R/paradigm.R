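#' Trial-paradigm specification
#'
#' Describes the cue-based (Graz-style) trial structure: every trial starts
#' with a rest interval and continues with a motor-imagery (MI) interval, so
#' each trial later contributes one REST and one MI analysis window.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param rest_duration Rest interval length in seconds.
#' @param mi_duration Motor-imagery interval length in seconds.
#' @param channels Ordered character vector of unique electrode labels.
#' @param n_trials Number of trials in a session. Each trial yields one window
#'   of each class, so this is also the number of decisions per class.
#'
#' @return An object of class `paradigm_spec`.
#' @export
#' @examples
#' paradigm_spec(n_trials = 10)
paradigm_spec <- function(sampling_rate = 256,
                          rest_duration = 3,
                          mi_duration = 5,
                          channels = bci_channels(),
                          n_trials = 60) {
  if (anyDuplicated(channels)) {
    abort("channel labels must be unique")
  }
  n_samples <- (rest_duration + mi_duration) * sampling_rate
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    abort("trial duration times sampling rate must be an integer sample count")
  }
  if (n_trials < 1) abort("n_trials must be >= 1")
  structure(
    list(
      sampling_rate = sampling_rate,
      rest_duration = rest_duration,
      mi_duration = mi_duration,
      channels = channels,
      n_trials = n_trials,
      n_samples = as.integer(round(n_samples))
    ),
    class = "paradigm_spec"
  )
}

#' Event-related desynchronization effect
#'
#' During motor imagery, band-limited power over sensorimotor channels drops
#' (ERD, typically in the mu 8-13 Hz and beta 14-30 Hz bands). `depth` is the
#' fractional power reduction: MI-segment band power at the target channels is
#' `(1 - depth)` times the rest-segment band power, in expectation.
#'
#' @param channels Target channel labels carrying the effect.
#' @param band Numeric length-2, band edges in Hz.
#' @param depth Fractional power reduction in `[0, 1]`.
#' @param onset_latency Seconds after the MI cue before the effect is fully
#'   established.
#'
#' @return An object of class `erd_effect`.
#' @export
erd_effect <- function(channels = c("C3", "C4"),
                       band = c(8, 12),
                       depth = 0.5,
                       onset_latency = 0.5) {
  if (depth < 0 || depth > 1) abort("depth must lie in [0, 1]")
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1]) {
    abort("band must be increasing positive edges (low, high) in Hz")
  }
  structure(
    list(channels = channels, band = band, depth = depth,
         onset_latency = onset_latency),
    class = "erd_effect"
  )
}

#' Background-EEG noise model
#'
#' Background activity is a sum of 1/f-shaped Gaussian noise, narrowband
#' oscillators (band-limited Gaussian processes), and an optional power-line
#' sinusoid, per channel.
#'
#' @param pink_sd Standard deviation (microvolts) of the 1/f component.
#' @param pink_exponent Spectral exponent: amplitude scales as `1/f^(exponent/2)`.
#' @param oscillations List of oscillators, each a list with elements `band`
#'   (Hz edges), `sd` (microvolts), and optionally `channels` (default: all).
#' @param line_freq Power-line frequency in Hz (`NULL` disables).
#' @param line_amplitude Line-noise sinusoid amplitude in microvolts.
#'
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(pink_sd = 10,
                       pink_exponent = 1,
                       oscillations = list(
                         list(band = c(8, 12), sd = 5),
                         list(band = c(16, 24), sd = 2.5)
                       ),
                       line_freq = 60,
                       line_amplitude = 1) {
  structure(
    list(pink_sd = pink_sd, pink_exponent = pink_exponent,
         oscillations = oscillations, line_freq = line_freq,
         line_amplitude = line_amplitude),
    class = "noise_spec"
  )
}

#' @export
print.paradigm_spec <- function(x, ...) {
  cat(sprintf(
    "<paradigm_spec> %d trials of %gs rest + %gs MI at %g Hz, %d channels\n",
    x$n_trials, x$rest_duration, x$mi_duration, x$sampling_rate,
    length(x$channels)
  ))
  invisible(x)
}
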