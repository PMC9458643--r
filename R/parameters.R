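#' Neuron labels of the startle circuit
#'
#' The circuit reduces each neuron category to a single node. Node order is
#' fixed throughout the package: 1 Ch (mechanosensory chordotonal input),
#' 2 Basin-1, 3 Basin-2, 4 iLNb and 5 iLNa (feedforward inhibitory local
#' interneurons), 6 Ha and 7 Hb (handle neurons).
#'
#' @format A character vector of length 7.
#' @export
neuron_labels <- c("Ch", "B1", "B2", "iLNb", "iLNa", "Ha", "Hb")

# resolve neuron identifiers (labels or 1-based indices) to indices
neuron_index <- function(x) {
  if (length(x) == 0) return(integer(0))
  if (is.numeric(x)) {
    idx <- as.integer(x)
    if (anyNA(idx) || any(idx < 1L | idx > 7L))
      abort("neuron indices must be integers in 1..7")
    return(idx)
  }
  idx <- match(as.character(x), neuron_labels)
  if (anyNA(idx))
    abort(paste0("unknown neuron label(s): ",
                 paste(setdiff(x, neuron_labels), collapse = ", ")))
  idx
}

# connectivity as printed: all synaptic weights are non-negative; the sign of
# a connection is carried by membership in the excitatory or inhibitory matrix
connectivity_matrices <- function(w_iLNa, w_iLNb) {
  A_ex <- matrix(0, 7, 7, dimnames = list(neuron_labels, neuron_labels))
  A_ex["B1", "Ch"] <- 2
  A_ex["B2", "Ch"] <- 1
  A_ex["iLNb", "Ch"] <- w_iLNb
  A_ex["iLNa", "Ch"] <- w_iLNa
  A_ex["Ha", "B1"] <- 0.2
  A_ex["Ha", "B2"] <- 0.2
  A_ex["Hb", "Ch"] <- 0.4
  A_ex["Hb", "B2"] <- 0.5

  A_in <- matrix(0, 7, 7, dimnames = list(neuron_labels, neuron_labels))
  A_in["B1", "iLNb"] <- 1.06
  A_in["B1", "iLNa"] <- 0.83
  A_in["B2", "iLNb"] <- 0.6
  A_in["B2", "iLNa"] <- 3.55
  A_in["iLNb", "iLNa"] <- 2.02
  A_in["iLNb", "Ha"] <- 1
  A_in["iLNb", "Hb"] <- 1.31
  A_in["iLNa", "iLNb"] <- 1.63
  A_in["iLNa", "Ha"] <- 0.66
  A_in["iLNa", "Hb"] <- 1.98
  A_in["Ha", "iLNb"] <- 1.1
  A_in["Ha", "iLNa"] <- 0.67
  A_in["Hb", "iLNb"] <- 1.04
  A_in["Hb", "iLNa"] <- 7.86
  list(A_ex = A_ex, A_in = A_in)
}

#' Circuit parameters of the larval startle rate model
#'
#' Assembles the full parameter set of the seven-node rate model: time
#' constants, activation thresholds, the saturation ceiling `r_max`, the
#' connectivity matrices, and the two chordotonal input weights `w_iLNa`
#' and `w_iLNb` that span the behavioural landscape.
#'
#' Two presets are available. `"adjusted"` is the parameter set tuned to
#' reproduce prepulse inhibition of the acoustic startle response
#' (`V0 = (0, 0.1, 0.1, 0.1, 0.1, 1, 5)`, `r_max = 15`,
#' `tau = (1, 30, ..., 30)`). `"jovanic"` is the original air-puff study
#' preset (`V0 = (0, 10, ..., 10)`, `r_max = 20`, `tau = (1, 35, ..., 35)`),
#' retained as an alternative regime; both share the same printed
#' connectivity. The high handle-neuron thresholds of the adjusted set
#' (`V0[Ha] = 1`, `V0[Hb] = 5`) are what allow prepulse-evoked interneuron
#' activity to persist into the subsequent pulse.
#'
#' @param preset `"adjusted"` or `"jovanic"`.
#' @param w_iLNa Chordotonal-to-iLNa weight, in `[0.5, 1.5]`.
#' @param w_iLNb Chordotonal-to-iLNb weight, in `[1.5, 2.5]`.
#' @param r_max Optional override of the maximum rate (positive scalar).
#'   Raising it models globally enhanced neurotransmitter release.
#' @param V0,tau Optional length-7 overrides of the activation thresholds
#'   and time constants (in rate units and arbitrary time units, AU).
#'
#' @return An object of class `circuit_parameters`: a list with elements
#'   `tau`, `V0`, `r_max`, `A_ex`, `A_in`, `w_iLNa`, `w_iLNb`, `preset`.
#' @examples
#' p <- circuit_parameters()
#' p$V0[["Hb"]]
#' p$A_in["B2", "iLNa"]
#' @export
circuit_parameters <- function(preset = c("adjusted", "jovanic"),
                               w_iLNa = 1, w_iLNb = 2,
                               r_max = NULL, V0 = NULL, tau = NULL) {
  preset <- match.arg(preset)
  base <- switch(preset,
    adjusted = list(V0 = c(0, 0.1, 0.1, 0.1, 0.1, 1, 5), r_max = 15,
                    tau = c(1, rep(30, 6))),
    jovanic  = list(V0 = c(0, rep(10, 6)), r_max = 20,
                    tau = c(1, rep(35, 6))))
  V0 <- V0 %||% base$V0
  tau <- tau %||% base$tau
  r_max <- r_max %||% base$r_max

  if (!is.numeric(w_iLNa) || length(w_iLNa) != 1 || w_iLNa < 0.5 || w_iLNa > 1.5)
    abort("`w_iLNa` must be a scalar in [0.5, 1.5]")
  if (!is.numeric(w_iLNb) || length(w_iLNb) != 1 || w_iLNb < 1.5 || w_iLNb > 2.5)
    abort("`w_iLNb` must be a scalar in [1.5, 2.5]")
  if (!is.numeric(r_max) || length(r_max) != 1 || r_max <= 0)
    abort("`r_max` must be a positive scalar")
  if (length(V0) != 7 || any(V0 < 0)) abort("`V0` must be 7 non-negative values")
  if (length(tau) != 7 || any(tau <= 0)) abort("`tau` must be 7 positive values")

  mats <- connectivity_matrices(w_iLNa, w_iLNb)
  structure(
    list(tau = setNames(as.numeric(tau), neuron_labels),
         V0 = setNames(as.numeric(V0), neuron_labels),
         r_max = as.numeric(r_max),
         A_ex = mats$A_ex, A_in = mats$A_in,
         w_iLNa = as.numeric(w_iLNa), w_iLNb = as.numeric(w_iLNb),
         preset = preset),
    class = "circuit_parameters")
}

# replace only the two chordotonal input weights (used by landscape sweeps)
set_input_weights <- function(params, w_iLNa = NULL, w_iLNb = NULL) {
  if (!is.null(w_iLNa)) {
    params$w_iLNa <- w_iLNa
    params$A_ex["iLNa", "Ch"] <- w_iLNa
  }
  if (!is.null(w_iLNb)) {
    params$w_iLNb <- w_iLNb
    params$A_ex["iLNb", "Ch"] <- w_iLNb
  }
  params
}

#' @export
print.circuit_parameters <- function(x, ...) {
  cat("<circuit_parameters> preset:", x$preset, "\n")
  cat("  r_max:", x$r_max,
      " w_iLNa:", x$w_iLNa, " w_iLNb:", x$w_iLNb, "\n")
  cat("  V0 :", paste(format(x$V0, trim = TRUE), collapse = " "), "\n")
  cat("  tau:", paste(format(x$tau, trim = TRUE), collapse = " "), "\n")
  invisible(x)
}
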