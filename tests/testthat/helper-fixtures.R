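# shared fixtures and a per-session cache for the heavier landscape sweeps
# (several acceptance checks reuse the same conditions)

adjusted <- circuit_parameters()
grid11 <- grid_spec(increment = 0.1)
grid5 <- grid_spec(increment = 0.25)

protocol45 <- function(prepulse = FALSE, lead = 30)
  stimulus_protocol(0.45, prepulse = prepulse, lead_interval = lead)

.sweep_cache <- new.env(parent = emptyenv())

cached_sweep <- function(key, expr) {
  if (is.null(.sweep_cache[[key]])) .sweep_cache[[key]] <- force(expr)
  .sweep_cache[[key]]
}

# classify one (w_iLNa, w_iLNb) point end to end
point_label <- function(w_iLNa, w_iLNb, prepulse = FALSE, lead = 30,
                        s1 = 0.45, r_max = NULL, silenced = character(),
                        dt = 0.05) {
  p <- circuit_parameters(w_iLNa = w_iLNa, w_iLNb = w_iLNb, r_max = r_max)
  traj <- simulate_circuit(
    p, stimulus_protocol(s1, prepulse = prepulse, lead_interval = lead),
    silenced = silenced, dt = dt)
  classify_behaviour(traj, reference = normalization_reference(p, dt = dt))$label
}

# rates at pulse onset for a with-prepulse run at one point
point_residuals <- function(w_iLNa, w_iLNb, lead = 30, r_max = NULL,
                            dt = 0.05) {
  p <- circuit_parameters(w_iLNa = w_iLNa, w_iLNb = w_iLNb, r_max = r_max)
  traj <- simulate_circuit(p, protocol45(prepulse = TRUE, lead = lead), dt = dt)
  on <- attr(traj, "protocol")$pulse_onset
  row <- traj[which.min(abs(traj$time - on)), ]
  setNames(as.numeric(row[neuron_labels]), neuron_labels)
}
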