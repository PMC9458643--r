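# analytic solution of the isolated Ch node (tau = 1, V0 = 0, no recurrent
# input): exponential charge toward the stimulus amplitude and exponential
# decay after offset
ch_closed_form <- function(t, on, off, amp) {
  r_off <- amp * (1 - exp(-(off - on)))
  ifelse(t < on, 0,
         ifelse(t < off, amp * (1 - exp(-(t - on))),
                r_off * exp(-(t - off))))
}

test_that("drive matches the rate equation at reference states", {
  p <- adjusted
  # rest state, no input: every component relaxes at -V0 / tau
  d0 <- circuit_drive(rep(0, 7), 0, p)
  expect_equal(unname(d0), unname(-p$V0 / p$tau))
  expect_true(all(d0 <= 0))
  # stimulus enters only through Ch (tau_Ch = 1, V0_Ch = 0)
  d1 <- circuit_drive(rep(0, 7), 0.45, p)
  expect_equal(d1[["Ch"]], 0.45)
  expect_equal(d1[-1], d0[-1])
  # silencing zeroes the derivative of the silenced neuron
  d2 <- circuit_drive(runif(7, 0, 5), 1, p, silenced = "iLNa")
  expect_identical(d2[["iLNa"]], 0)
})

test_that("a zero-amplitude protocol leaves the rectified rest state at zero", {
  traj <- simulate_circuit(adjusted, stimulus_protocol(0), dt = 0.1)
  expect_true(all(as.matrix(traj[neuron_labels]) == 0))
})

test_that("the Ch node follows its piecewise-exponential closed form", {
  traj <- simulate_circuit(adjusted, stimulus_protocol(0.45))
  prot <- attr(traj, "protocol")
  expected <- ch_closed_form(traj$time, prot$pulse_onset,
                             prot$pulse_onset + prot$pulse_duration, 0.45)
  expect_lt(max(abs(traj$Ch - expected)), 1e-6)
  # with a prepulse the same piecewise form applies segment by segment
  trajp <- simulate_circuit(adjusted, stimulus_protocol(0.45, prepulse = TRUE))
  pp <- ch_closed_form(trajp$time, 20, 24, 0.45)
  carry <- pp[trajp$time == 54][1]  # residual entering the pulse segment
  expected_p <- ifelse(trajp$time < 54, pp,
                       0.45 + (carry - 0.45) * exp(-(trajp$time - 54)))
  expected_p[trajp$time >= 104] <-
    expected_p[trajp$time == 104][1] * exp(-(trajp$time[trajp$time >= 104] - 104))
  expect_lt(max(abs(trajp$Ch - expected_p)), 1e-6)
})

test_that("rates stay within [0, r_max] across stimuli and presets", {
  cases <- expand.grid(s1 = c(0.45, 1, 2), preset = c("adjusted", "jovanic"),
                       stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cases))) {
    p <- circuit_parameters(cases$preset[k], w_iLNa = 1.5, w_iLNb = 2.5)
    traj <- simulate_circuit(p, stimulus_protocol(cases$s1[k], prepulse = TRUE),
                             dt = 0.1)
    r <- as.matrix(traj[neuron_labels])
    expect_true(all(r >= 0))
    expect_true(all(r <= p$r_max))
  }
})

test_that("silenced neurons are exactly zero throughout", {
  traj <- simulate_circuit(adjusted, stimulus_protocol(2), silenced = "iLNa",
                           dt = 0.1)
  expect_true(all(traj$iLNa == 0))
  expect_true(any(traj$iLNb > 0))
  all7 <- simulate_circuit(adjusted, stimulus_protocol(2),
                           silenced = neuron_labels, dt = 0.1)
  expect_true(all(as.matrix(all7[neuron_labels]) == 0))
})

test_that("identical inputs give bit-identical trajectories", {
  a <- simulate_circuit(adjusted, protocol45(TRUE), dt = 0.1)
  b <- simulate_circuit(adjusted, protocol45(TRUE), dt = 0.1)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("halving the step changes the final state below tolerance", {
  for (prot in list(stimulus_protocol(0.45, prepulse = TRUE),
                    stimulus_protocol(2))) {
    a <- simulate_circuit(adjusted, prot, dt = 0.1)
    b <- simulate_circuit(adjusted, prot, dt = 0.05)
    fa <- as.numeric(a[nrow(a), neuron_labels])
    fb <- as.numeric(b[nrow(b), neuron_labels])
    expect_lt(max(abs(fa - fb)), 1e-4)
  }
})

test_that("invalid initial states and steps are rejected", {
  expect_error(simulate_circuit(adjusted, protocol45(), dt = 0), "dt")
  expect_error(simulate_circuit(adjusted, protocol45(), r0 = rep(-1, 7)),
               "r0")
  expect_error(simulate_circuit(adjusted, protocol45(), r0 = rep(99, 7)),
               "r0")
})

test_that("a diverging integration reports the failing time point", {
  p <- circuit_parameters(r_max = 1e300)
  expect_error(simulate_circuit(p, stimulus_protocol(2), dt = 10),
               "non-finite state at t")
})
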