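#' Behaviour labels used by the classifier
#'
#' Instantaneous labels are `"hunch"`, `"bend"` and `"n.r."` (no reaction);
#' trial outcomes additionally include the two sequence categories.
#'
#' @format Character vectors.
#' @export
behaviour_levels <- c("hunch", "bend", "n.r.", "hunch-bend-seq", "bend-hunch-seq")

#' Classifier thresholds
#'
#' The behaviour-selection rule compares the Basin activities normalized by
#' a [normalization_reference()]: writing `B1h = B1 / r*_B1` and
#' `B2h = B2 / r*_B2`, a time point is no-reaction when both normalized
#' activities are at or below `activity_threshold`; otherwise the ratio
#' `B2h / B1h` selects hunch (ratio below `ratio_threshold`, Basin-1
#' dominant) or bend (co-activation). Bouts shorter than `cutoff` are
#' discarded, which turns weak transient responses into no-reaction.
#'
#' `rule = "ratio_first"` (default) evaluates the no-reaction condition
#' first and assigns every remaining point by the ratio, making the
#' partition of the `(B1h, B2h)` plane exhaustive; if `B1h` is zero in the
#' ratio branch the ratio is treated as infinite (bend). `rule = "literal"`
#' instead requires both normalized activities to exceed
#' `activity_threshold` for hunch and bend, leaving mixed cases as
#' no-reaction.
#'
#' @param ratio_threshold Hunch/bend boundary on `B2h / B1h` (default 0.8).
#' @param activity_threshold No-reaction threshold on normalized activity
#'   (default 0.5).
#' @param cutoff Minimum bout duration in AU (default 10).
#' @param rule `"ratio_first"` or `"literal"`.
#' @return An object of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(ratio_threshold = 0.8,
                                  activity_threshold = 0.5,
                                  cutoff = 10,
                                  rule = c("ratio_first", "literal")) {
  rule <- match.arg(rule)
  stopifnot(ratio_threshold > 0, activity_threshold > 0, cutoff > 0)
  structure(list(ratio_threshold = ratio_threshold,
                 activity_threshold = activity_threshold,
                 cutoff = cutoff, rule = rule),
            class = "classifier_thresholds")
}

#' Normalization reference for behaviour classification
#'
#' The classifier normalizes each Basin activity by its maximum `r*_i`
#' attained in a reference condition: the circuit at `w_iLNa = 1`,
#' `w_iLNb = 2` driven by a sustained stimulus `s1 = 0.5` (no prepulse, no
#' silencing). The reference input is held on long enough (default 500 AU)
#' for the response to saturate, so `r*` is the plateau of the reference
#' response; the approach to the plateau is monotone, hence the maximum
#' over the run equals the steady state.
#'
#' References are cached per parameter set (including `r_max`), so altering
#' any parameter triggers recomputation. Pass `reference_protocol` to use a
#' different reference stimulus.
#'
#' @param params A [circuit_parameters()] object supplying everything
#'   except the reference input weights.
#' @param s1 Reference stimulus amplitude (default 0.5).
#' @param w_iLNa,w_iLNb Reference input weights (defaults 1 and 2).
#' @param reference_protocol Optional [stimulus_protocol()] overriding the
#'   sustained default.
#' @param duration Reference stimulus duration in AU (default 500).
#' @param dt Integration step (default 0.05).
#'
#' @return An object of class `normalization_reference` with element
#'   `r_star`, a named length-7 vector of per-neuron maxima.
#' @examples
#' ref <- normalization_reference(circuit_parameters())
#' ref$r_star[c("B1", "B2")]
#' @export
normalization_reference <- function(params, s1 = 0.5, w_iLNa = 1, w_iLNb = 2,
                                    reference_protocol = NULL,
                                    duration = 500, dt = 0.05) {
  stopifnot(inherits(params, "circuit_parameters"))
  protocol <- reference_protocol %||%
    stimulus_protocol(pulse_amplitude = s1, pulse_duration = duration,
                      prepulse = FALSE, prepulse_onset = 0,
                      prepulse_duration = 0, lead_interval = 0,
                      response_tail = 10)
  ref_params <- set_input_weights(params, w_iLNa, w_iLNb)
  key <- rlang::hash(list(ref_params, protocol, dt))
  cached <- the$reference_cache[[key]]
  if (!is.null(cached)) return(cached)

  sim <- integrate_batch(ref_params, protocol, w_iLNa, w_iLNb, dt = dt)
  r_star <- setNames(sim$maxima[, 1], neuron_labels)
  if (r_star[["B1"]] == 0 || r_star[["B2"]] == 0)
    abort("degenerate normalization reference: Basin maximum is zero")
  out <- structure(list(r_star = r_star, s1 = s1,
                        w_iLNa = w_iLNa, w_iLNb = w_iLNb,
                        protocol = protocol, dt = dt,
                        params_hash = rlang::hash(ref_params)),
                   class = "normalization_reference")
  the$reference_cache[[key]] <- out
  out
}

#' @export
print.normalization_reference <- function(x, ...) {
  cat("<normalization_reference> s1 =", x$s1,
      " (w_iLNa, w_iLNb) = (", x$w_iLNa, ",", x$w_iLNb, ")\n")
  print(round(x$r_star, 4))
  invisible(x)
}

# instantaneous integer codes: 0 n.r., 1 hunch, 2 bend (vectorized over
# matrices or vectors of normalized activities)
label_codes <- function(B1h, B2h, th) {
  if (th$rule == "ratio_first") {
    ratio <- ifelse(B1h == 0, Inf, B2h / B1h)
    out <- ifelse(B1h <= th$activity_threshold & B2h <= th$activity_threshold,
                  0L, ifelse(ratio < th$ratio_threshold, 1L, 2L))
  } else {
    both <- B1h > th$activity_threshold & B2h > th$activity_threshold
    ratio <- ifelse(B1h == 0, Inf, B2h / B1h)
    out <- ifelse(both, ifelse(ratio < th$ratio_threshold, 1L, 2L), 0L)
  }
  out
}

#' Instantaneous behaviour labels along a trajectory
#'
#' Applies the behaviour-selection conditions point by point: normalized
#' Basin activities are compared against the activity threshold and their
#' ratio against the hunch/bend boundary (see [classifier_thresholds()]).
#'
#' @param trajectory A [simulate_circuit()] result.
#' @param reference A [normalization_reference()]; computed from the
#'   trajectory's own parameters when omitted.
#' @param thresholds A [classifier_thresholds()].
#' @return A tibble with columns `time`, `B1_hat`, `B2_hat` and `label`
#'   (factor with levels hunch, bend, n.r.).
#' @export
behaviour_labels <- function(trajectory, reference = NULL,
                             thresholds = classifier_thresholds()) {
  stopifnot(inherits(trajectory, "circuit_trajectory"))
  reference <- reference %||%
    normalization_reference(attr(trajectory, "params"), dt = attr(trajectory, "dt"))
  B1h <- trajectory$B1 / reference$r_star[["B1"]]
  B2h <- trajectory$B2 / reference$r_star[["B2"]]
  code <- label_codes(B1h, B2h, thresholds)
  tibble(time = trajectory$time, B1_hat = B1h, B2_hat = B2h,
         label = factor(c("n.r.", "hunch", "bend")[code + 1L],
                        levels = behaviour_levels[1:3]))
}

# outcome + bouts from an integer code series on a uniform grid.
# A bout is a maximal run of one behaviour; its duration is run length * dt
# (each sample stands for [t, t + dt)). Bouts shorter than the cut-off are
# discarded; surviving bouts determine the outcome.
outcome_from_codes <- function(code, t0, dt, cutoff) {
  r <- rle(as.integer(code))
  n <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_beh <- r$values > 0L
  dur <- r$lengths * dt
  bouts <- tibble(
    label = c("hunch", "bend")[r$values[is_beh]],
    start = t0 + (starts[is_beh] - 1L) * dt,
    end = t0 + ends[is_beh] * dt,
    duration = dur[is_beh],
    survives = dur[is_beh] >= cutoff - 1e-9)
  surv <- bouts$label[bouts$survives]
  label <- if (length(surv) == 0) "n.r."
  else {
    u <- unique(surv)
    if (length(u) == 1) u else paste0(u[1], "-", u[2], "-seq")
  }
  list(label = label, bouts = bouts)
}

#' Classify a trial from its label series
#'
#' Restricts the instantaneous label series to the response window
#' (from `window_start`, by default the pulse onset), extracts maximal
#' hunch/bend bouts, discards bouts shorter than the cut-off, and derives
#' the trial outcome: `n.r.` if no bout survives, the common label if all
#' surviving bouts agree, otherwise a sequence ordered by first occurrence.
#'
#' @param labels A tibble from [behaviour_labels()] (columns `time`,
#'   `label`).
#' @param thresholds A [classifier_thresholds()] (supplies the cut-off).
#' @param window_start Start of the classification window in AU.
#' @param window_end Optional end of the window (defaults to the end of the
#'   series).
#' @return An object of class `trial_outcome`: list with `label`, `bouts`
#'   (including discarded ones, flagged by `survives`), `window`.
#' @export
classify_trial <- function(labels, thresholds = classifier_thresholds(),
                           window_start, window_end = NULL) {
  stopifnot(is.data.frame(labels), all(c("time", "label") %in% names(labels)))
  window_end <- window_end %||% max(labels$time)
  sel <- labels$time >= window_start & labels$time <= window_end
  if (!any(sel)) abort("empty classification window")
  tt <- labels$time[sel]
  dt <- if (length(tt) > 1) tt[2] - tt[1] else stop("window holds a single point")
  code <- match(as.character(labels$label[sel]), c("n.r.", "hunch", "bend")) - 1L
  res <- outcome_from_codes(code, tt[1], dt, thresholds$cutoff)
  structure(list(label = res$label, bouts = res$bouts,
                 window = c(start = tt[1], end = window_end),
                 thresholds = thresholds),
            class = "trial_outcome")
}

#' Simulate-and-classify convenience wrapper
#'
#' Computes instantaneous labels for a trajectory and classifies the
#' response to the pulse (window starting at pulse onset).
#'
#' @inheritParams behaviour_labels
#' @param window_start Classification window start; defaults to the
#'   protocol's pulse onset.
#' @param window_end Optional window end.
#' @return A `trial_outcome` whose `labels` element keeps the full
#'   instantaneous series for plotting.
#' @examples
#' p <- circuit_parameters(w_iLNa = 0.95, w_iLNb = 2.45)
#' traj <- simulate_circuit(p, stimulus_protocol(0.45))
#' classify_behaviour(traj)$label
#' @export
classify_behaviour <- function(trajectory, reference = NULL,
                               thresholds = classifier_thresholds(),
                               window_start = NULL, window_end = NULL) {
  labels <- behaviour_labels(trajectory, reference, thresholds)
  window_start <- window_start %||% attr(trajectory, "protocol")$pulse_onset
  out <- classify_trial(labels, thresholds, window_start, window_end)
  out$labels <- labels
  out
}

#' @export
print.trial_outcome <- function(x, ...) {
  cat("<trial_outcome>", x$label, "\n")
  surv <- x$bouts[x$bouts$survives, ]
  cat(sprintf("  %d bout(s), %d surviving the %g AU cut-off\n",
              nrow(x$bouts), nrow(surv), x$thresholds$cutoff))
  if (nrow(surv)) print(surv)
  invisible(x)
}
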