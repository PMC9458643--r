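#' Instantaneous drive of the rate model
#'
#' Evaluates the right-hand side of the circuit's rate equation
#' \deqn{\tau_i \, dr_i/dt = -V_{0,i} - r_i + s_i
#'   + (r^{max} - r_i)\sum_j A^{ex}_{ij} r_j - \sum_j A^{in}_{ij} r_j}
#' for one state vector. Only the Ch node receives stimulus (`s1`);
#' excitation saturates as the rate approaches `r_max`. Derivatives of
#' silenced neurons are forced to zero.
#'
#' @param r Length-7 rate vector, component-wise in `[0, r_max]`.
#' @param s1 Scalar stimulus to the Ch node.
#' @param params A [circuit_parameters()] object.
#' @param silenced Neuron labels or indices to silence (empty by default).
#' @return Named length-7 vector of derivatives `dr/dt`.
#' @examples
#' p <- circuit_parameters()
#' circuit_drive(rep(0, 7), s1 = 0.45, p)
#' @export
circuit_drive <- function(r, s1, params, silenced = character()) {
  stopifnot(inherits(params, "circuit_parameters"))
  if (length(r) != 7) abort("`r` must have 7 components")
  sil <- neuron_index(silenced)
  s <- c(s1, rep(0, 6))
  exc <- drop(params$A_ex %*% r)
  inh <- drop(params$A_in %*% r)
  d <- (-params$V0 - r + s + (params$r_max - r) * exc - inh) / params$tau
  if (length(sil)) d[sil] <- 0
  setNames(d, neuron_labels)
}

# non-zero connectivity triplets shared by every simulation; the two
# chordotonal input weights (A_ex rows iLNb/iLNa, column Ch) vary per grid
# point and are applied separately
fixed_coupling <- function(params) {
  A_ex <- params$A_ex
  A_ex["iLNb", "Ch"] <- 0
  A_ex["iLNa", "Ch"] <- 0
  idx_ex <- which(A_ex != 0, arr.ind = TRUE)
  idx_in <- which(params$A_in != 0, arr.ind = TRUE)
  list(ex = cbind(idx_ex, w = A_ex[idx_ex]),
       inh = cbind(idx_in, w = params$A_in[idx_in]))
}

# RK4 integration of G grid points at once. State is a 7 x G matrix; the
# coupling sums are accumulated term by term in a fixed order so that every
# column's arithmetic is identical to a single-point run (grid results must
# not depend on batching). The stimulus is sampled at the left node of each
# step: the waveform is piecewise constant, so whenever switch times are
# multiples of dt each step lies entirely within one constant-stimulus
# segment and RK4 retains its full order across onsets/offsets.
integrate_batch <- function(params, protocol, w_iLNa, w_iLNb,
                            silenced = character(), dt = 0.05, r0 = NULL,
                            full = FALSE) {
  stopifnot(inherits(params, "circuit_parameters"),
            inherits(protocol, "stimulus_protocol"))
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) abort("`dt` must be > 0")
  G <- length(w_iLNa)
  stopifnot(length(w_iLNb) == G, G >= 1)
  sil <- neuron_index(silenced)

  times <- seq(0, protocol$total_time, by = dt)
  nT <- length(times)
  sv <- stimulus_waveform(protocol, times)
  V0 <- unname(params$V0); tau <- unname(params$tau); r_max <- params$r_max
  cp <- fixed_coupling(params)
  ex <- cp$ex; inh <- cp$inh

  R <- matrix(0, 7, G)
  if (!is.null(r0)) {
    if (length(r0) != 7) abort("`r0` must have 7 components")
    if (any(r0 < 0) || any(r0 > r_max)) abort("`r0` must lie in [0, r_max]")
    R[] <- r0
  }
  if (length(sil)) R[sil, ] <- 0

  drv <- function(R, s1) {
    E <- matrix(0, 7, G)
    for (k in seq_len(nrow(ex)))
      E[ex[k, 1], ] <- E[ex[k, 1], ] + ex[k, 3] * R[ex[k, 2], ]
    E[4, ] <- E[4, ] + w_iLNb * R[1, ]
    E[5, ] <- E[5, ] + w_iLNa * R[1, ]
    I <- matrix(0, 7, G)
    for (k in seq_len(nrow(inh)))
      I[inh[k, 1], ] <- I[inh[k, 1], ] + inh[k, 3] * R[inh[k, 2], ]
    dR <- -V0 - R + (r_max - R) * E - I
    dR[1, ] <- dR[1, ] + s1
    dR <- dR / tau
    if (length(sil)) dR[sil, ] <- 0
    dR
  }

  b1 <- matrix(0, nT, G); b2 <- matrix(0, nT, G)
  b1[1, ] <- R[2, ]; b2[1, ] <- R[3, ]
  rates <- if (full) matrix(0, nT, 7) else NULL
  if (full) rates[1, ] <- R[, 1]
  maxima <- R
  resid <- R
  i_on <- which.min(abs(times - protocol$pulse_onset))

  for (k in seq_len(nT - 1)) {
    s <- sv[k]
    # sub-stage states are rectified before each drive evaluation: rates are
    # non-negative by definition, so the vector field is only ever evaluated
    # at feasible states; this keeps bout boundaries first-order clean where
    # a rate sits on the zero constraint
    k1 <- drv(R, s)
    k2 <- drv(pmax(R + dt / 2 * k1, 0), s)
    k3 <- drv(pmax(R + dt / 2 * k2, 0), s)
    k4 <- drv(pmax(R + dt * k3, 0), s)
    R <- R + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    R[R < 0] <- 0
    if (length(sil)) R[sil, ] <- 0
    if (!all(is.finite(R)))
      abort(sprintf("non-finite state at t = %g during integration", times[k + 1]))
    if (k + 1 == i_on) resid <- R
    b1[k + 1, ] <- R[2, ]; b2[k + 1, ] <- R[3, ]
    if (full) rates[k + 1, ] <- R[, 1]
    maxima <- pmax(maxima, R)
  }

  list(times = times, stimulus = sv, B1 = b1, B2 = b2, rates = rates,
       residual = resid, maxima = maxima,
       pulse_onset = times[i_on], dt = dt)
}

#' Simulate the startle circuit
#'
#' Integrates the seven-node rate model under a stimulus protocol with the
#' classic fourth-order Runge-Kutta scheme. After every full step each rate
#' is rectified to `max(0, r)`, implementing the non-negativity of firing
#' rates; silenced neurons are clamped to zero rate and zero derivative for
#' the whole run.
#'
#' @param params A [circuit_parameters()] object.
#' @param protocol A [stimulus_protocol()].
#' @param silenced Neuron labels or indices to silence.
#' @param dt Integration step in AU (default 0.05). Stimulus switch times
#'   should be multiples of `dt`; the rectangular waveform is sampled at
#'   the left node of each step.
#' @param r0 Initial rates (default: all zero, the rectified resting state).
#'
#' @return A `circuit_trajectory`: a tibble with columns `time`,
#'   `stimulus` and one rate column per neuron (`Ch`, `B1`, `B2`, `iLNb`,
#'   `iLNa`, `Ha`, `Hb`), carrying the parameters and protocol as
#'   attributes.
#' @examples
#' p <- circuit_parameters(w_iLNa = 0.95, w_iLNb = 2.45)
#' traj <- simulate_circuit(p, stimulus_protocol(0.45), dt = 0.1)
#' dplyr::filter(traj, time == 80)
#' @export
simulate_circuit <- function(params, protocol, silenced = character(),
                             dt = 0.05, r0 = NULL) {
  sim <- integrate_batch(params, protocol, params$w_iLNa, params$w_iLNb,
                         silenced = silenced, dt = dt, r0 = r0, full = TRUE)
  out <- as_tibble(as.data.frame(sim$rates, col.names = neuron_labels))
  names(out) <- neuron_labels
  out <- tibble(time = sim$times, stimulus = sim$stimulus)[, c("time", "stimulus")] |>
    dplyr::bind_cols(out)
  structure(out,
            class = c("circuit_trajectory", class(tibble())),
            params = params, protocol = protocol,
            silenced = neuron_labels[neuron_index(silenced)], dt = dt)
}

#' @export
print.circuit_trajectory <- function(x, ...) {
  p <- attr(x, "protocol")
  cat(sprintf("<circuit_trajectory> %d time points, dt = %g AU\n",
              nrow(x), attr(x, "dt")))
  if (!is.null(p))
    cat(sprintf("  pulse s1 = %g at t = %g; prepulse %s\n",
                p$pulse_amplitude, p$pulse_onset,
                if (p$prepulse) "enabled" else "disabled"))
  if (length(attr(x, "silenced")))
    cat("  silenced:", paste(attr(x, "silenced"), collapse = ", "), "\n")
  NextMethod()
}
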