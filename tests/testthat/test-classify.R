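# independent brute-force bout scanner used as an oracle for the
# run-length-based classifier: walks the series index by index
scan_outcome <- function(lab, dt, cutoff) {
  bouts <- list()
  i <- 1; n <- length(lab)
  while (i <= n) {
    if (lab[i] != "n.r.") {
      j <- i
      while (j < n && lab[j + 1] == lab[i]) j <- j + 1
      bouts[[length(bouts) + 1]] <- list(label = lab[i], len = j - i + 1)
      i <- j + 1
    } else i <- i + 1
  }
  surv <- vapply(bouts, function(b) b$len * dt >= cutoff - 1e-9, logical(1))
  labs <- vapply(bouts, function(b) b$label, character(1))[surv]
  if (length(labs) == 0) return("n.r.")
  u <- unique(labs)
  if (length(u) == 1) u else paste0(u[1], "-", u[2], "-seq")
}

fake_labels <- function(lab, dt = 1) {
  tibble::tibble(time = seq_along(lab) * dt,
                 label = factor(lab, levels = behaviour_levels[1:3]))
}

test_that("normalization reference reflects the reference condition", {
  ref <- normalization_reference(adjusted)
  expect_gt(ref$r_star[["B1"]], 0)
  expect_gt(ref$r_star[["B2"]], 0)
  # deterministic across calls
  expect_identical(ref$r_star, normalization_reference(adjusted)$r_star)
  # changing r_max changes the reference (cache keys on the parameter set)
  ref20 <- normalization_reference(circuit_parameters(r_max = 20))
  expect_false(all(ref20$r_star == ref$r_star))
  # maxima saturate: doubling the reference duration leaves r* unchanged
  ref_long <- normalization_reference(adjusted, duration = 1000)
  expect_equal(ref_long$r_star, ref$r_star, tolerance = 1e-6)
})

test_that("a reference without Basin activity is degenerate", {
  expect_error(normalization_reference(adjusted, s1 = 0), "degenerate")
})

test_that("instantaneous rule partitions the normalized activity plane", {
  th <- classifier_thresholds()
  # both sub-threshold: no reaction
  expect_equal(label_codes(0, 0, th), 0L)
  expect_equal(label_codes(0.5, 0.5, th), 0L)
  # Basin-1 dominant: hunch (ratio 0.6 < 0.8)
  expect_equal(label_codes(1.0, 0.6, th), 1L)
  # co-activation: bend (ratio 1 >= 0.8)
  expect_equal(label_codes(0.9, 0.9, th), 2L)
  # mixed case under the default rule goes by the ratio
  expect_equal(label_codes(0.7, 0.2, th), 1L)
  expect_equal(label_codes(0.2, 0.7, th), 2L)
  # zero Basin-1 with active Basin-2: ratio treated as infinite -> bend
  expect_equal(label_codes(0, 0.7, th), 2L)
  # literal rule sends mixed cases to n.r. instead
  thl <- classifier_thresholds(rule = "literal")
  expect_equal(label_codes(0.7, 0.2, thl), 0L)
  expect_equal(label_codes(1.0, 0.6, thl), 1L)
  expect_equal(label_codes(0, 0, thl), 0L)
})

test_that("trial outcomes follow bout extraction and the cut-off", {
  th <- classifier_thresholds()  # cutoff 10
  # all-n.r. series
  expect_equal(classify_trial(fake_labels(rep("n.r.", 50)), th, 0)$label, "n.r.")
  # a hunch bout of 8 AU dies at the 10 AU cut-off
  lab <- c(rep("n.r.", 5), rep("hunch", 8), rep("n.r.", 20))
  expect_equal(classify_trial(fake_labels(lab), th, 0)$label, "n.r.")
  # hunch 15 AU then bend 20 AU: hunch-bend sequence
  lab <- c(rep("hunch", 15), rep("bend", 20))
  out <- classify_trial(fake_labels(lab), th, 0)
  expect_equal(out$label, "hunch-bend-seq")
  expect_equal(nrow(out$bouts), 2)
  # reverse order gives the other sequence
  lab <- c(rep("bend", 15), rep("hunch", 20))
  expect_equal(classify_trial(fake_labels(lab), th, 0)$label, "bend-hunch-seq")
  # two surviving hunch bouts split by a gap still classify as hunch
  lab <- c(rep("hunch", 12), rep("n.r.", 5), rep("hunch", 12))
  expect_equal(classify_trial(fake_labels(lab), th, 0)$label, "hunch")
  # window restriction: a bout before the window does not count
  lab <- c(rep("hunch", 15), rep("n.r.", 30))
  expect_equal(classify_trial(fake_labels(lab), th, window_start = 20)$label,
               "n.r.")
  expect_error(classify_trial(fake_labels(lab), th, window_start = 999),
               "empty classification window")
})

test_that("classifier agrees with a brute-force scanner on random series", {
  set.seed(42)
  th <- classifier_thresholds(cutoff = 4)
  for (k in 1:60) {
    lab <- sample(c("n.r.", "hunch", "bend"), 80, replace = TRUE,
                  prob = c(0.5, 0.3, 0.2))
    got <- classify_trial(fake_labels(lab), th, 0)$label
    expect_identical(got, scan_outcome(lab, 1, 4))
  }
})

test_that("raising the cut-off only moves outcomes toward n.r.", {
  set.seed(7)
  rank0 <- function(l) if (l == "n.r.") 0 else if (grepl("seq", l)) 2 else 1
  for (k in 1:40) {
    lab <- sample(c("n.r.", "hunch", "bend"), 60, replace = TRUE)
    prev <- classify_trial(fake_labels(lab), classifier_thresholds(cutoff = 2), 0)$label
    for (cutoff in c(5, 10, 20)) {
      cur <- classify_trial(fake_labels(lab), classifier_thresholds(cutoff = cutoff), 0)$label
      expect_lte(rank0(cur), rank0(prev))
      # no new behaviour label appears that was absent at the lower cut-off
      if (cur != "n.r.")
        expect_true(all(strsplit(sub("-seq", "", cur), "-")[[1]] %in%
                          strsplit(sub("-seq", "", prev), "-")[[1]]))
      prev <- cur
    }
  }
})

test_that("classify_behaviour windows the response at pulse onset", {
  p <- circuit_parameters(w_iLNa = 0.95, w_iLNb = 2.45)
  out <- classify_behaviour(simulate_circuit(p, protocol45()))
  expect_equal(out$label, "hunch")
  expect_equal(unname(out$window["start"]),
               stimulus_protocol(0.45)$pulse_onset)
  expect_true(all(out$bouts$end > out$bouts$start))
})
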