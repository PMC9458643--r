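test_that("grid enumeration is inclusive and validated", {
  g <- grid_spec(increment = 0.1)
  pts <- grid_points(g)
  expect_equal(nrow(pts), 121)
  expect_true(all(c(0.5, 1.5) %in% pts$w_iLNa))
  expect_true(all(c(1.5, 2.5) %in% pts$w_iLNb))
  expect_equal(nrow(grid_points(grid_spec())), 101 * 101)
  expect_error(grid_spec(increment = 0), "increment")
  expect_error(grid_spec(w_iLNa = c(0, 1)), "w_iLNa")
})

test_that("a stimulus-free landscape is all no-reaction", {
  land <- sweep_landscape(grid5, adjusted, stimulus_protocol(0), dt = 0.1)
  expect_true(all(land$label == "n.r."))
  expect_equal(glance(land)$startle, 0)
})

test_that("sweeps equal independent per-point simulation and classification", {
  g <- grid_spec(w_iLNa = c(0.9, 1.1), w_iLNb = c(2.3, 2.5), increment = 0.1)
  land <- sweep_landscape(g, adjusted, protocol45(TRUE))
  # batching must not matter either
  land_chunked <- sweep_landscape(g, adjusted, protocol45(TRUE), chunk_size = 2)
  expect_identical(as.data.frame(land), as.data.frame(land_chunked))
  for (k in seq_len(nrow(land))) {
    expect_identical(
      as.character(land$label[k]),
      point_label(land$w_iLNa[k], land$w_iLNb[k], prepulse = TRUE))
  }
})

test_that("fractions sum to one and groupings follow their schemes", {
  land <- cached_sweep("l45_no_pp_11",
                       sweep_landscape(grid11, adjusted, protocol45()))
  fr <- behaviour_fractions(land)
  expect_equal(sum(fr$fraction), 1)
  ff <- behaviour_fractions(land, "first_behaviour")
  expect_equal(sum(ff$fraction), 1)
  fs <- behaviour_fractions(land, "startle")
  expect_equal(sum(fs$fraction), 1)
  expect_equal(fs$fraction[fs$group == "n.r."],
               fr$fraction[fr$group == "n.r."])
  expect_error(behaviour_fractions(land, "by-area"), "unknown grouping")
})

test_that("change maps pair conditions and flag transitions", {
  no_pp <- cached_sweep("l45_no_pp_11",
                        sweep_landscape(grid11, adjusted, protocol45()))
  with_pp <- cached_sweep("l45_pp_11",
                          sweep_landscape(grid11, adjusted, protocol45(TRUE)))
  cm <- change_map(no_pp, with_pp)
  expect_equal(nrow(cm), nrow(no_pp))
  expect_true(any(cm$changed))
  # identical inputs: all "no change"
  cm0 <- change_map(no_pp, no_pp)
  expect_true(all(cm0$change == "no change"))
  # mismatched grids are rejected
  other <- sweep_landscape(grid5, adjusted, protocol45(TRUE), dt = 0.1)
  expect_error(change_map(no_pp, other), "different grids")
  # mismatched conditions beyond the prepulse are rejected
  sil <- sweep_landscape(grid5, adjusted, protocol45(TRUE),
                         silenced = "Hb", dt = 0.1)
  base5 <- sweep_landscape(grid5, adjusted, protocol45(), dt = 0.1)
  expect_error(change_map(base5, sil), "beyond the prepulse")
})

test_that("persistence maps record residual activity at pulse onset", {
  g <- grid_spec(w_iLNa = c(0.9, 1.0), w_iLNb = c(2.4, 2.5), increment = 0.05)
  pm <- persistence_map(g, adjusted, protocol45(TRUE))
  expect_setequal(as.character(unique(pm$neuron)), neuron_labels)
  expect_true(all(pm$residual >= 0))
  # matches a single-trajectory read-out at the same point
  res <- point_residuals(0.95, 2.45)
  sub <- dplyr::filter(pm, w_iLNa == 0.95, w_iLNb == 2.45)
  expect_equal(setNames(sub$residual, as.character(sub$neuron)), res)
  # a zero-amplitude prepulse leaves no residual anywhere
  quiet <- stimulus_protocol(0.45, prepulse = TRUE, prepulse_amplitude = 0)
  pm0 <- persistence_map(g, adjusted, quiet)
  expect_true(all(pm0$residual == 0))
  # prepulse-less protocols are a contract violation
  expect_error(persistence_map(g, adjusted, protocol45(FALSE)), "prepulse")
})

test_that("lead-interval sweeps include a baseline and validate input", {
  g <- grid5
  sw <- lead_interval_sweep(g, adjusted, protocol45(TRUE),
                            intervals = c(30, 150), dt = 0.1)
  expect_equal(nrow(sw), 3)
  base <- sw$startle_fraction[sw$condition == "no-prepulse"]
  # an interval long enough for all residuals to decay matches baseline
  expect_equal(sw$startle_fraction[which(sw$lead_interval == 150)], base)
  expect_error(lead_interval_sweep(g, adjusted, protocol45(TRUE),
                                   intervals = numeric(0)), "non-empty")
  expect_error(lead_interval_sweep(g, adjusted, protocol45(TRUE),
                                   intervals = -5), ">= 0")
})

test_that("silencing experiments compare against an unsilenced control", {
  sil <- silencing_experiment(grid5, adjusted,
                              targets = list("iLNa", c("iLNa", "Hb")),
                              dt = 0.1)
  expect_equal(sil$target, c("none", "iLNa", "iLNa+Hb"))
  expect_error(silencing_experiment(grid5, adjusted, targets = list()),
               "non-empty")
  # silencing the whole circuit leaves no reaction anywhere
  all_sil <- silencing_experiment(grid5, adjusted,
                                  targets = list(neuron_labels), dt = 0.1)
  expect_equal(all_sil$nr[all_sil$target != "none"], 1)
})

test_that("rmax experiments are deterministic and validated", {
  rx <- rmax_experiment(grid5, adjusted, protocol45(TRUE),
                        r_max_values = c(15, 15), dt = 0.1)
  expect_identical(rx[1, -1], rx[2, -1])
  expect_error(rmax_experiment(grid5, adjusted, protocol45(TRUE),
                               r_max_values = c(15, 0)), "positive")
})
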