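#' Rectangular stimulus protocol for the chordotonal input
#'
#' Describes the stimulus waveform `s1(t)` delivered to the Ch node: a
#' rectangular pulse, optionally preceded by a shorter rectangular prepulse.
#' All other nodes receive no direct stimulus. Times are in the model's
#' arbitrary units (AU).
#'
#' The pulse onset is placed at
#' `prepulse_onset + prepulse_duration + lead_interval` (lead interval
#' measured from prepulse offset to pulse onset, the default) or at
#' `prepulse_onset + lead_interval` (onset-to-onset). The onset is computed
#' the same way whether or not the prepulse is enabled, so that paired
#' with/without-prepulse runs are aligned in time.
#'
#' @param pulse_amplitude Pulse strength `s1`, in `[0, 2]`.
#' @param pulse_duration Pulse length in AU (default 50).
#' @param prepulse Logical; deliver a prepulse before the pulse?
#' @param prepulse_amplitude Prepulse strength; defaults to
#'   `pulse_amplitude` (the prepulse differs from the pulse only in
#'   duration).
#' @param prepulse_duration Prepulse length in AU (default 4).
#' @param lead_interval Gap in AU between prepulse and pulse (default 30);
#'   interpreted according to `lead_mode`.
#' @param prepulse_onset Prepulse start time in AU (default 20).
#' @param lead_mode `"offset_to_onset"` (default) or `"onset_to_onset"`.
#' @param response_tail AU of simulated time kept after pulse offset so that
#'   activities can relax back toward baseline (default 150).
#' @param total_time Optional override of the simulation horizon; must cover
#'   the pulse.
#'
#' @return An object of class `stimulus_protocol` with the computed
#'   `pulse_onset` and `total_time`.
#' @examples
#' stimulus_protocol(pulse_amplitude = 0.45, prepulse = TRUE)
#' @export
stimulus_protocol <- function(pulse_amplitude,
                              pulse_duration = 50,
                              prepulse = FALSE,
                              prepulse_amplitude = NULL,
                              prepulse_duration = 4,
                              lead_interval = 30,
                              prepulse_onset = 20,
                              lead_mode = c("offset_to_onset", "onset_to_onset"),
                              response_tail = 150,
                              total_time = NULL) {
  lead_mode <- match.arg(lead_mode)
  prepulse_amplitude <- prepulse_amplitude %||% pulse_amplitude

  if (!is.numeric(pulse_amplitude) || length(pulse_amplitude) != 1 ||
      pulse_amplitude < 0 || pulse_amplitude > 2)
    abort("`pulse_amplitude` must be a scalar in [0, 2]")
  if (prepulse_amplitude < 0) abort("`prepulse_amplitude` must be >= 0")
  if (pulse_duration <= 0) abort("`pulse_duration` must be positive")
  if (prepulse_duration < 0) abort("`prepulse_duration` must be >= 0")
  if (lead_interval < 0) abort("`lead_interval` must be >= 0")
  if (prepulse_onset < 0) abort("`prepulse_onset` must be >= 0")

  pulse_onset <- prepulse_onset + lead_interval +
    if (lead_mode == "offset_to_onset") prepulse_duration else 0
  if (prepulse && lead_mode == "onset_to_onset" &&
      prepulse_onset + prepulse_duration > pulse_onset)
    abort("prepulse overlaps the pulse under `onset_to_onset` lead mode")

  total_time <- total_time %||% (pulse_onset + pulse_duration + response_tail)
  if (total_time < pulse_onset + pulse_duration)
    abort("`total_time` must cover the pulse")

  structure(
    list(pulse_amplitude = pulse_amplitude,
         pulse_duration = pulse_duration,
         prepulse = isTRUE(prepulse),
         prepulse_amplitude = prepulse_amplitude,
         prepulse_duration = prepulse_duration,
         lead_interval = lead_interval,
         prepulse_onset = prepulse_onset,
         lead_mode = lead_mode,
         pulse_onset = pulse_onset,
         total_time = total_time),
    class = "stimulus_protocol")
}

#' Evaluate the stimulus waveform
#'
#' Returns `s1(t)` at the requested time points. The waveform is
#' piecewise-constant and left-continuous: each stimulus is on over
#' `[onset, onset + duration)`.
#'
#' @param protocol A [stimulus_protocol()].
#' @param times Numeric vector of time points (AU).
#' @return Numeric vector of stimulus values.
#' @export
stimulus_waveform <- function(protocol, times) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  s <- numeric(length(times))
  on <- protocol$pulse_onset
  s[times >= on & times < on + protocol$pulse_duration] <- protocol$pulse_amplitude
  if (protocol$prepulse) {
    pon <- protocol$prepulse_onset
    sel <- times >= pon & times < pon + protocol$prepulse_duration
    s[sel] <- protocol$prepulse_amplitude
  }
  s
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("<stimulus_protocol>\n")
  cat(sprintf("  pulse: s1 = %g for %g AU from t = %g\n",
              x$pulse_amplitude, x$pulse_duration, x$pulse_onset))
  if (x$prepulse)
    cat(sprintf("  prepulse: s1 = %g for %g AU from t = %g (lead %g, %s)\n",
                x$prepulse_amplitude, x$prepulse_duration, x$prepulse_onset,
                x$lead_interval, x$lead_mode))
  else cat("  prepulse: disabled\n")
  cat(sprintf("  total_time: %g AU\n", x$total_time))
  invisible(x)
}
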