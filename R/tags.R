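#' Tagging-frequency configuration
#'
#' Holds the two stimulation frequencies of a rapid invisible frequency
#' tagging (RIFT) design: an auditory amplitude-modulation frequency and a
#' visual luminance-modulation frequency, together with the modulation depth,
#' the phase at stimulus onset and the sampling rate of the waveform grid.
#' Both modulations are phase-locked across trials: the phase at tagging
#' onset is identical in every trial.
#'
#' @param f_audio auditory tag frequency in Hz (default 54).
#' @param f_visual visual tag frequency in Hz (default 68).
#' @param modulation_depth modulation depth as a fraction in \[0, 1\]
#'   (0 = unmodulated carrier, 1 = full depth).
#' @param phase_at_onset phase of both modulations at tagging onset, radians.
#' @param sample_rate sampling rate in Hz of the discrete waveform grid.
#' @return an object of class `rift_tag_config`.
#' @export
tag_config <- function(f_audio = 54, f_visual = 68, modulation_depth = 1,
                       phase_at_onset = 0, sample_rate = 1000) {
  stopifnot(length(f_audio) == 1L, length(f_visual) == 1L,
            is.numeric(f_audio), is.numeric(f_visual),
            length(sample_rate) == 1L, sample_rate > 0)
  if (f_audio <= 0 || f_visual <= 0) stopf("tag frequencies must be positive")
  if (f_audio == f_visual) stopf("f_audio and f_visual must differ")
  nyquist <- sample_rate / 2
  if (f_audio >= nyquist || f_visual >= nyquist) {
    stopf("tag frequency at or above the Nyquist rate (%g Hz): aliasing", nyquist)
  }
  if (f_visual - f_audio < 1) {
    stopf("f_visual - f_audio must be at least 1 Hz so the difference intermodulation lands on the 1 Hz analysis grid")
  }
  if (!is.numeric(modulation_depth) || modulation_depth < 0 || modulation_depth > 1) {
    stopf("modulation_depth must lie in [0, 1]")
  }
  structure(list(f_audio = f_audio, f_visual = f_visual,
                 modulation_depth = modulation_depth,
                 phase_at_onset = phase_at_onset,
                 sample_rate = sample_rate),
            class = "rift_tag_config")
}

#' @export
print.rift_tag_config <- function(x, ...) {
  cat(sprintf("<rift_tag_config> audio %g Hz, visual %g Hz, depth %g, phase %g rad, fs %g Hz\n",
              x$f_audio, x$f_visual, x$modulation_depth, x$phase_at_onset,
              x$sample_rate))
  invisible(x)
}

tag_time_grid <- function(duration, sample_rate) {
  n <- round(duration * sample_rate)
  if (n < 1) stopf("duration too short for the sample rate")
  (seq_len(n) - 1) / sample_rate
}

#' Visual luminance-modulation waveform
#'
#' The luminance tag multiplies pixel luminance by
#' `0.5 * (1 + depth * sin(2 * pi * f_visual * t + phase))`, a unit-range
#' waveform in \[0, 1\] whose mean is 0.5. With `depth = 0` the waveform is
#' the constant 0.5 (no modulation). The waveform is deterministic:
#' identical arguments give identical samples (phase-locked across trials).
#'
#' @param duration waveform duration in seconds (> 0).
#' @param tag a [tag_config].
#' @return numeric vector of `round(duration * sample_rate)` samples in \[0, 1\].
#' @export
make_luminance_tag <- function(duration, tag = tag_config()) {
  stopifnot(inherits(tag, "rift_tag_config"))
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    stopf("duration must be a positive scalar")
  }
  if (tag$f_visual >= tag$sample_rate / 2) {
    stopf("f_visual at or above Nyquist: aliasing")
  }
  t <- tag_time_grid(duration, tag$sample_rate)
  0.5 * (1 + tag$modulation_depth *
           sin(2 * pi * tag$f_visual * t + tag$phase_at_onset))
}

#' Auditory amplitude-modulation tagging
#'
#' Multiplies an audio envelope, sampled at the tag's sample rate, by the
#' auditory modulation waveform
#' `0.5 * (1 + depth * sin(2 * pi * f_audio * t + phase))`. Length is
#' preserved.
#'
#' @param audio_envelope numeric sample series at `tag$sample_rate`.
#' @param tag a [tag_config].
#' @return the amplitude-tagged series, same length as the input.
#' @export
make_amplitude_tag <- function(audio_envelope, tag = tag_config()) {
  stopifnot(inherits(tag, "rift_tag_config"))
  if (length(audio_envelope) == 0L) stopf("empty audio envelope")
  if (tag$f_audio >= tag$sample_rate / 2) {
    stopf("f_audio at or above Nyquist: aliasing")
  }
  t <- (seq_along(audio_envelope) - 1) / tag$sample_rate
  audio_envelope * 0.5 * (1 + tag$modulation_depth *
                            sin(2 * pi * tag$f_audio * t + tag$phase_at_onset))
}

#' Achievable presentation rate of a quadrant/color-channel frame schedule
#'
#' DLP projectors can interpret the four quadrants and three color channels
#' of each GPU frame as twelve successive monochrome frames, so a display
#' refreshing at `refresh` Hz reaches
#' `refresh * n_quadrants * n_color_channels` presentations per second. The
#' result bounds which tag frequencies the scheduler can represent.
#'
#' @param refresh GPU refresh rate in Hz (positive integer).
#' @param n_quadrants number of quadrants packed per frame (positive integer).
#' @param n_color_channels number of color channels packed (positive integer).
#' @return the presentation rate in Hz.
#' @export
frame_schedule_rate <- function(refresh, n_quadrants, n_color_channels) {
  if (!is_count(refresh) || !is_count(n_quadrants) || !is_count(n_color_channels)) {
    stopf("refresh, n_quadrants and n_color_channels must be positive integers")
  }
  refresh * n_quadrants * n_color_channels
}
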