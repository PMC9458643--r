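#' Grid over the chordotonal input-weight plane
#'
#' The behavioural landscape is evaluated on a regular grid over the
#' `w_iLNb`-`w_iLNa` plane, which stands in for inter-individual
#' variability in how strongly the chordotonal input drives the two
#' inhibitory interneuron classes. Endpoints are inclusive; the default
#' 0.01 increment yields the full 101 x 101 grid.
#'
#' @param w_iLNa Range for `w_iLNa` (within `[0.5, 1.5]`).
#' @param w_iLNb Range for `w_iLNb` (within `[1.5, 2.5]`).
#' @param increment Grid step on both axes (default 0.01).
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(increment = 0.1)  # 11 x 11
#' @export
grid_spec <- function(w_iLNa = c(0.5, 1.5), w_iLNb = c(1.5, 2.5),
                      increment = 0.01) {
  if (!is.numeric(increment) || length(increment) != 1 || increment <= 0)
    abort("`increment` must be a positive scalar")
  stopifnot(length(w_iLNa) == 2, length(w_iLNb) == 2,
            w_iLNa[1] <= w_iLNa[2], w_iLNb[1] <= w_iLNb[2])
  if (w_iLNa[1] < 0.5 || w_iLNa[2] > 1.5)
    abort("`w_iLNa` range must lie within [0.5, 1.5]")
  if (w_iLNb[1] < 1.5 || w_iLNb[2] > 2.5)
    abort("`w_iLNb` range must lie within [1.5, 2.5]")
  structure(list(w_iLNa = as.numeric(w_iLNa), w_iLNb = as.numeric(w_iLNb),
                 increment = increment),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  pts <- grid_points(x)
  cat(sprintf("<grid_spec> w_iLNa [%g, %g] x w_iLNb [%g, %g], step %g (%d points)\n",
              x$w_iLNa[1], x$w_iLNa[2], x$w_iLNb[1], x$w_iLNb[2],
              x$increment, nrow(pts)))
  invisible(x)
}

#' Enumerate the grid points of a grid specification
#'
#' @param grid A [grid_spec()].
#' @return A tibble with columns `w_iLNa` and `w_iLNb` (endpoints
#'   inclusive, `w_iLNa` varying fastest).
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  # round to the grid resolution so accumulated float error cannot drop an
  # inclusive endpoint
  wa <- round(seq(grid$w_iLNa[1], grid$w_iLNa[2], by = grid$increment), 10)
  wb <- round(seq(grid$w_iLNb[1], grid$w_iLNb[2], by = grid$increment), 10)
  tidyr::expand_grid(w_iLNb = wb, w_iLNa = wa)[, c("w_iLNa", "w_iLNb")]
}

# integrate + classify a set of grid points in memory-bounded chunks;
# returns outcome labels and the 7 x G matrix of rates at pulse onset
sweep_codes <- function(points, params, protocol, silenced, thresholds,
                        reference, dt, chunk_size = 2500) {
  G <- nrow(points)
  labels <- character(G)
  residual <- matrix(0, 7, G, dimnames = list(neuron_labels, NULL))
  chunks <- split(seq_len(G), ceiling(seq_len(G) / chunk_size))
  for (idx in chunks) {
    sim <- integrate_batch(params, protocol,
                           points$w_iLNa[idx], points$w_iLNb[idx],
                           silenced = silenced, dt = dt)
    sel <- sim$times >= protocol$pulse_onset
    B1h <- sim$B1[sel, , drop = FALSE] / reference$r_star[["B1"]]
    B2h <- sim$B2[sel, , drop = FALSE] / reference$r_star[["B2"]]
    code <- label_codes(B1h, B2h, thresholds)
    t0 <- sim$times[sel][1]
    for (j in seq_along(idx))
      labels[idx[j]] <-
        outcome_from_codes(code[, j], t0, dt, thresholds$cutoff)$label
    residual[, idx] <- sim$residual
  }
  list(labels = labels, residual = residual)
}

#' Sweep the behavioural landscape
#'
#' Simulates and classifies every grid point of the `w_iLNb`-`w_iLNa`
#' plane under one condition (protocol, silencing, parameter set). Each
#' point is an independent trial; results do not depend on traversal order
#' or batching. One normalization reference, computed from `params`, is
#' shared by the whole sweep.
#'
#' @param grid A [grid_spec()].
#' @param params A [circuit_parameters()]; its `w_iLNa`/`w_iLNb` are
#'   replaced point by point.
#' @param protocol A [stimulus_protocol()].
#' @param silenced Neuron labels or indices silenced for the whole sweep.
#' @param thresholds A [classifier_thresholds()].
#' @param reference Optional [normalization_reference()]; computed from
#'   `params` when omitted.
#' @param dt Integration step (default 0.05).
#' @param chunk_size Grid points integrated per batch (memory bound).
#'
#' @return A `behaviour_landscape`: tibble with columns `w_iLNa`,
#'   `w_iLNb`, `label` (factor over the five outcome levels), carrying the
#'   condition as attributes.
#' @examples
#' land <- sweep_landscape(grid_spec(increment = 0.25),
#'                         circuit_parameters(),
#'                         stimulus_protocol(0.45))
#' behaviour_fractions(land)
#' @export
sweep_landscape <- function(grid, params, protocol, silenced = character(),
                            thresholds = classifier_thresholds(),
                            reference = NULL, dt = 0.05, chunk_size = 2500) {
  stopifnot(inherits(grid, "grid_spec"))
  reference <- reference %||% normalization_reference(params, dt = dt)
  pts <- grid_points(grid)
  res <- sweep_codes(pts, params, protocol, silenced, thresholds,
                     reference, dt, chunk_size)
  out <- mutate(pts, label = factor(res$labels, levels = behaviour_levels))
  structure(out,
            class = c("behaviour_landscape", class(tibble())),
            grid = grid, params = params, protocol = protocol,
            silenced = neuron_labels[neuron_index(silenced)],
            thresholds = thresholds, dt = dt,
            r_star = reference$r_star)
}

#' @export
print.behaviour_landscape <- function(x, ...) {
  cat(sprintf("<behaviour_landscape> %d grid points; prepulse %s\n",
              nrow(x),
              if (attr(x, "protocol")$prepulse) "enabled" else "disabled"))
  if (length(attr(x, "silenced")))
    cat("  silenced:", paste(attr(x, "silenced"), collapse = ", "), "\n")
  tab <- table(x$label)
  cat("  ", paste(sprintf("%s %.3f", names(tab), tab / nrow(x)), collapse = "  "), "\n")
  NextMethod()
}

# one-row tibble of label fractions plus the derived groups used by the
# figure-level summaries
fractions_wide <- function(label) {
  f <- function(l) mean(label == l)
  tibble(
    hunch = f("hunch"), bend = f("bend"), nr = f("n.r."),
    hunch_bend_seq = f("hunch-bend-seq"), bend_hunch_seq = f("bend-hunch-seq"),
    hunch_first = f("hunch") + f("hunch-bend-seq"),
    bend_first = f("bend") + f("bend-hunch-seq"),
    hunch_seq = f("hunch") + f("hunch-bend-seq") + f("bend-hunch-seq"),
    bend_seq = f("bend") + f("hunch-bend-seq") + f("bend-hunch-seq"),
    startle = 1 - f("n.r."))
}

#' Behaviour fractions of a landscape
#'
#' Fraction of grid area occupied by each behaviour (or behaviour group)
#' under a grouping scheme: `"label"` keeps the five outcome labels;
#' `"first_behaviour"` counts sequences with their first behaviour
#' (hunch + hunch-bend sequence, bend + bend-hunch sequence, n.r.), the
#' scheme used when comparing with scored behavioural experiments;
#' `"with_sequences"` counts both sequence types into both the hunch and
#' the bend group (groups overlap, so these fractions need not sum to 1);
#' `"startle"` splits startle (any non-n.r. outcome) from n.r.
#'
#' @param landscape A [sweep_landscape()] result.
#' @param grouping Grouping scheme name.
#' @return A tibble with columns `group`, `n_points`, `fraction`.
#' @export
behaviour_fractions <- function(landscape,
                                grouping = c("label", "first_behaviour",
                                             "with_sequences", "startle")) {
  stopifnot(inherits(landscape, "behaviour_landscape"))
  if (is.character(grouping) && length(grouping) == 1 &&
      !grouping %in% c("label", "first_behaviour", "with_sequences", "startle"))
    abort(paste0("unknown grouping: ", grouping))
  grouping <- match.arg(grouping)
  lab <- as.character(landscape$label)
  n <- length(lab)
  groups <- switch(grouping,
    label = lapply(setNames(nm = behaviour_levels), function(l) lab == l),
    first_behaviour = list(
      "hunch + hunch-bend-seq" = lab %in% c("hunch", "hunch-bend-seq"),
      "bend + bend-hunch-seq" = lab %in% c("bend", "bend-hunch-seq"),
      "n.r." = lab == "n.r."),
    with_sequences = list(
      "hunch + seq" = lab %in% c("hunch", "hunch-bend-seq", "bend-hunch-seq"),
      "bend + seq" = lab %in% c("bend", "hunch-bend-seq", "bend-hunch-seq"),
      "n.r." = lab == "n.r."),
    startle = list(
      startle = lab != "n.r.",
      "n.r." = lab == "n.r."))
  tibble(group = names(groups),
         n_points = vapply(groups, sum, integer(1)),
         fraction = vapply(groups, mean, numeric(1)))
}

# conditions must agree on everything except the prepulse toggle
stop_unless_paired <- function(a, b) {
  if (!identical(list(a$w_iLNa, a$w_iLNb), list(b$w_iLNa, b$w_iLNb)))
    abort("landscapes were computed on different grids")
  pa <- attr(a, "protocol"); pb <- attr(b, "protocol")
  pa$prepulse <- pb$prepulse <- NULL
  if (!identical(pa, pb) ||
      !identical(attr(a, "params"), attr(b, "params")) ||
      !identical(attr(a, "silenced"), attr(b, "silenced")) ||
      !identical(attr(a, "thresholds"), attr(b, "thresholds")))
    abort("landscapes differ in condition beyond the prepulse")
  invisible(TRUE)
}

#' Prepulse change map
#'
#' Pairs the outcome of each grid point without and with a prepulse and
#' labels the transition (e.g. `hunch -> n.r.`), the grid-level picture of
#' where prepulse inhibition acts.
#'
#' @param no_pp,with_pp Two [sweep_landscape()] results on the identical
#'   grid and condition, without and with the prepulse.
#' @return A `ppi_change_map` tibble with columns `w_iLNa`, `w_iLNb`,
#'   `before`, `after`, `change` and logical `changed`.
#' @export
change_map <- function(no_pp, with_pp) {
  stopifnot(inherits(no_pp, "behaviour_landscape"),
            inherits(with_pp, "behaviour_landscape"))
  stop_unless_paired(no_pp, with_pp)
  out <- tibble(
    w_iLNa = no_pp$w_iLNa, w_iLNb = no_pp$w_iLNb,
    before = no_pp$label, after = with_pp$label,
    changed = as.character(no_pp$label) != as.character(with_pp$label))
  out$change <- ifelse(out$changed,
                       paste(out$before, "->", out$after), "no change")
  structure(out[, c("w_iLNa", "w_iLNb", "before", "after", "change", "changed")],
            class = c("ppi_change_map", class(tibble())))
}

#' Residual-activity (persistence) map
#'
#' For every grid point, records each neuron's rate at the moment the
#' pulse begins in a with-prepulse run: the activity induced by the
#' prepulse that persists through the lead interval. Persistent iLNb
#' activity at pulse onset is the proposed mechanism of prepulse
#' inhibition.
#'
#' @inheritParams sweep_landscape
#' @param protocol A [stimulus_protocol()] with `prepulse = TRUE`.
#' @param normalized Divide each neuron's residual by its reference
#'   maximum `r*`? Default `FALSE` (raw rates).
#' @return A `ppi_persistence_map` tibble with columns `w_iLNa`,
#'   `w_iLNb`, `neuron` (factor in circuit order) and `residual`.
#' @export
persistence_map <- function(grid, params, protocol, silenced = character(),
                            normalized = FALSE, reference = NULL,
                            dt = 0.05, chunk_size = 2500) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!isTRUE(protocol$prepulse))
    abort("persistence requires a protocol with `prepulse = TRUE`")
  reference <- reference %||% normalization_reference(params, dt = dt)
  pts <- grid_points(grid)
  res <- sweep_codes(pts, params, protocol, silenced,
                     classifier_thresholds(), reference, dt, chunk_size)
  resid <- res$residual
  if (normalized) resid <- resid / reference$r_star
  out <- tidyr::pivot_longer(
    dplyr::bind_cols(pts, as_tibble(t(resid))),
    cols = dplyr::all_of(neuron_labels),
    names_to = "neuron", values_to = "residual")
  out$neuron <- factor(out$neuron, levels = neuron_labels)
  structure(out, class = c("ppi_persistence_map", class(tibble())),
            normalized = normalized, protocol = protocol)
}

#' Lead-interval dependence of prepulse inhibition
#'
#' Sweeps the landscape for each lead interval (plus a no-prepulse
#' baseline) and summarises the startle area fraction (any non-n.r.
#' outcome) and its suppression relative to baseline. Prepulse inhibition
#' typically shows an inverted-U dependence: suppression is weaker when
#' the lead interval is too short or too long.
#'
#' @inheritParams sweep_landscape
#' @param protocol A [stimulus_protocol()] template; its lead interval is
#'   replaced per sweep.
#' @param intervals Lead intervals in AU (default `c(10, 30, 50)`).
#' @return A `lead_interval_sweep` tibble with one baseline row
#'   (`lead_interval = NA`) and one row per interval, columns `condition`,
#'   `lead_interval`, `startle_fraction`, `suppression`.
#' @export
lead_interval_sweep <- function(grid, params, protocol,
                                intervals = c(10, 30, 50),
                                thresholds = classifier_thresholds(),
                                reference = NULL, dt = 0.05,
                                chunk_size = 2500) {
  if (length(intervals) == 0) abort("`intervals` must be non-empty")
  if (any(intervals < 0)) abort("lead intervals must be >= 0")
  reference <- reference %||% normalization_reference(params, dt = dt)
  remake <- function(lead, prepulse) {
    stimulus_protocol(
      pulse_amplitude = protocol$pulse_amplitude,
      pulse_duration = protocol$pulse_duration,
      prepulse = prepulse,
      prepulse_amplitude = protocol$prepulse_amplitude,
      prepulse_duration = protocol$prepulse_duration,
      lead_interval = lead,
      prepulse_onset = protocol$prepulse_onset,
      lead_mode = protocol$lead_mode)
  }
  startle <- function(lead, prepulse) {
    land <- sweep_landscape(grid, params, remake(lead, prepulse),
                            thresholds = thresholds, reference = reference,
                            dt = dt, chunk_size = chunk_size)
    mean(land$label != "n.r.")
  }
  base <- startle(protocol$lead_interval, FALSE)
  rows <- purrr::map_dfr(intervals, function(L) {
    st <- startle(L, TRUE)
    tibble(condition = paste0("lead-", L), lead_interval = L,
           startle_fraction = st, suppression = base - st)
  })
  out <- bind_rows(
    tibble(condition = "no-prepulse", lead_interval = NA_real_,
           startle_fraction = base, suppression = NA_real_),
    rows)
  structure(out, class = c("lead_interval_sweep", class(tibble())))
}

#' In silico neuron-silencing experiment
#'
#' Re-runs the behavioural landscape with selected neurons silenced
#' (rates clamped to zero) and tabulates behaviour fractions against the
#' unsilenced control on the same grid. The classic comparisons silence
#' iLNa (hunching collapses, bending expands) or Hb (the reverse) under a
#' strong stimulus (`s1 = 2`, no prepulse).
#'
#' @inheritParams sweep_landscape
#' @param protocol A [stimulus_protocol()]; defaults to the strong-pulse
#'   protocol `stimulus_protocol(pulse_amplitude = 2)`.
#' @param targets List of neuron sets to silence, e.g.
#'   `list("iLNa", "Hb")`; each element may name several neurons.
#' @return A tibble with one control row (`target = "none"`) and one row
#'   per target, holding label fractions and the grouped fractions
#'   (`hunch_seq`, `bend_seq` include both sequence categories).
#' @export
silencing_experiment <- function(grid, params,
                                 protocol = stimulus_protocol(pulse_amplitude = 2),
                                 targets = list("iLNa", "Hb"),
                                 thresholds = classifier_thresholds(),
                                 reference = NULL, dt = 0.05,
                                 chunk_size = 2500) {
  if (length(targets) == 0) abort("`targets` must be non-empty")
  reference <- reference %||% normalization_reference(params, dt = dt)
  one <- function(silenced, name) {
    land <- sweep_landscape(grid, params, protocol, silenced = silenced,
                            thresholds = thresholds, reference = reference,
                            dt = dt, chunk_size = chunk_size)
    dplyr::bind_cols(tibble(target = name), fractions_wide(land$label))
  }
  bind_rows(
    one(character(), "none"),
    purrr::map_dfr(targets, function(tg)
      one(tg, paste(neuron_labels[neuron_index(tg)], collapse = "+"))))
}

#' Maximum-rate (r_max) manipulation experiment
#'
#' Raising the saturation ceiling `r_max` models globally enhanced
#' neurotransmitter release (the CenG1A loss-of-function surrogate). For
#' each `r_max` the landscape is swept with and without the prepulse and
#' the prepulse-induced suppression of the startle area is reported; a
#' smaller suppression at higher `r_max` reproduces the reduced prepulse
#' inhibition of the mutant.
#'
#' @inheritParams sweep_landscape
#' @param r_max_values Positive saturation ceilings to compare
#'   (default `c(15, 20)`).
#' @param refit_reference Recompute the normalization reference under each
#'   `r_max` (default) or freeze the base-parameter reference.
#' @return A tibble with one row per `r_max`: startle fractions without
#'   and with prepulse and their difference `suppression`.
#' @export
rmax_experiment <- function(grid, params, protocol,
                            r_max_values = c(15, 20),
                            refit_reference = TRUE,
                            thresholds = classifier_thresholds(),
                            dt = 0.05, chunk_size = 2500) {
  if (length(r_max_values) == 0 || any(r_max_values <= 0))
    abort("`r_max_values` must be positive")
  if (!isTRUE(protocol$prepulse))
    protocol$prepulse <- TRUE  # the comparison needs the with-prepulse arm
  base_ref <- normalization_reference(params, dt = dt)
  purrr::map_dfr(r_max_values, function(rm) {
    p <- params
    p$r_max <- rm
    ref <- if (refit_reference) normalization_reference(p, dt = dt) else base_ref
    no_pp <- protocol; no_pp$prepulse <- FALSE
    st <- function(prot) {
      land <- sweep_landscape(grid, p, prot, thresholds = thresholds,
                              reference = ref, dt = dt,
                              chunk_size = chunk_size)
      mean(land$label != "n.r.")
    }
    a <- st(no_pp); b <- st(protocol)
    tibble(r_max = rm, startle_no_prepulse = a, startle_with_prepulse = b,
           suppression = a - b)
  })
}
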