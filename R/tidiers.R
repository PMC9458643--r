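#' Tidy a circuit trajectory into long form
#'
#' @param x A `circuit_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `neuron` (factor in circuit
#'   order) and `rate`.
#' @method tidy circuit_trajectory
#' @export
tidy.circuit_trajectory <- function(x, ...) {
  out <- tidyr::pivot_longer(as_tibble(x), cols = dplyr::all_of(neuron_labels),
                             names_to = "neuron", values_to = "rate")
  out$neuron <- factor(out$neuron, levels = neuron_labels)
  out[, c("time", "neuron", "rate", "stimulus")]
}

#' One-row summary of a circuit trajectory
#'
#' @param x A `circuit_trajectory`.
#' @param ... Unused.
#' @return A tibble with the peak rate per neuron (columns `peak_<label>`),
#'   the step size and horizon.
#' @method glance circuit_trajectory
#' @export
glance.circuit_trajectory <- function(x, ...) {
  peaks <- vapply(neuron_labels, function(l) max(x[[l]]), numeric(1))
  dplyr::bind_cols(
    tibble::as_tibble_row(setNames(peaks, paste0("peak_", neuron_labels))),
    tibble(dt = attr(x, "dt"), total_time = max(x$time),
           pulse_onset = attr(x, "protocol")$pulse_onset))
}

#' Tidy a trial outcome into its bout records
#'
#' @param x A `trial_outcome`.
#' @param ... Unused.
#' @return The bout tibble (`label`, `start`, `end`, `duration`,
#'   `survives`).
#' @method tidy trial_outcome
#' @export
tidy.trial_outcome <- function(x, ...) x$bouts

#' One-row summary of a trial outcome
#'
#' @param x A `trial_outcome`.
#' @param ... Unused.
#' @method glance trial_outcome
#' @export
glance.trial_outcome <- function(x, ...) {
  tibble(label = x$label,
         n_bouts = nrow(x$bouts),
         n_surviving = sum(x$bouts$survives),
         window_start = x$window[["start"]],
         window_end = x$window[["end"]])
}

#' Tidy a behavioural landscape
#'
#' @param x A `behaviour_landscape`.
#' @param ... Unused.
#' @return The landscape as a plain tibble (`w_iLNa`, `w_iLNb`, `label`).
#' @method tidy behaviour_landscape
#' @export
tidy.behaviour_landscape <- function(x, ...) as_tibble(x)

#' One-row fraction summary of a behavioural landscape
#'
#' @param x A `behaviour_landscape`.
#' @param ... Unused.
#' @return A tibble with the label fractions, grouped fractions and the
#'   startle area fraction.
#' @method glance behaviour_landscape
#' @export
glance.behaviour_landscape <- function(x, ...) {
  dplyr::bind_cols(tibble(n_points = nrow(x)), fractions_wide(x$label))
}
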