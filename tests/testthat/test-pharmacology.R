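test_that("Ki law reproduces the clinical dose anchors", {
  expect_equal(ki_from_inhibition(10, 0.40), 15)
  expect_equal(round(ki_from_inhibition(16, 0.35)), 30)
  expect_equal(ki_from_inhibition(12, 0.40), 18)
  expect_equal(ki_from_inhibition(7, 0.5), 7)   # half-inhibition point
  expect_error(ki_from_inhibition(10, 0), "\\(0, 1\\)")
  expect_error(ki_from_inhibition(10, 1), "\\(0, 1\\)")
})

test_that("dose <-> inhibition are exact inverses", {
  expect_equal(inhibition_from_dose(0, 30), 0)
  expect_equal(inhibition_from_dose(30, 30), 0.5)
  expect_equal(inhibition_from_dose(8, 30), 8 / 38, tolerance = 1e-12)
  for (l in c(0.1, 0.35, 0.5, 0.9)) {
    D <- 12
    expect_equal(inhibition_from_dose(D, ki_from_inhibition(D, l)), l,
                 tolerance = 1e-12)
  }
})

test_that("AChE inhibition scales the ACh half-life as tau0/(1-l)", {
  expect_equal(scaled_ach_halflife(0, 5), 5)
  expect_equal(scaled_ach_halflife(0.40, 5), 25 / 3, tolerance = 1e-12)
  expect_equal(scaled_ach_halflife(8 / 38, 5), 6.333, tolerance = 1e-3)
  expect_error(scaled_ach_halflife(1), "\\[0, 1\\)")
})

test_that("cleft molecule counts span the published volume range", {
  expect_equal(molecules_in_cleft(1e-6, 5e-17), 30)
  expect_equal(molecules_in_cleft(1e-6, 2e-16), 120)
  expect_equal(molecules_in_cleft(0, 1e-16), 0)
})

test_that("dose chain presets carry the printed clinical Ki values", {
  tab <- ache_inhibitors()
  expect_setequal(tab$drug, c("donepezil", "galantamine", "rivastigmine"))
  expect_equal(tab$Ki_mg[tab$drug == "donepezil"], 15)
  expect_equal(tab$Ki_mg[tab$drug == "galantamine"], 30)
  expect_equal(tab$Ki_mg[tab$drug == "rivastigmine"], 18)
  ch <- ache_dose_chain("donepezil", 10)
  expect_equal(ch$inhibition, 0.4)
  expect_equal(ch$halflife_ms, 25 / 3, tolerance = 1e-12)
  expect_error(ache_dose_chain("aspirin", 100), "known")
})

test_that("simulated tracer displacement matches the static competition closed form", {
  kon <- 2e-6
  nt <- ligand("NT", "neurotransmitter", kon = kon, Kd = 120)
  tracer <- ligand("T", "tracer", kon = kon, Kd = 2, concentration = 1)
  drug <- ligand("D", "drug", kon = kon, Kd = 30, concentration = 0)
  # static case: no firing, constant NT at the equilibration level
  cfg <- synapse_config(list(receptor_pool(list(nt, tracer, drug), name = "post")),
                        tonic_rate_hz = 0, nt_halflife_ms = 1e12,
                        quantal_increment_nM = 0, equilibration_nM = 100,
                        transient_s = 1, averaging_s = 2, dt_ms = 0.02)
  ex <- tracer_experiment(cfg, "post", "T", "D")
  expect_equal(simulate_displacement(ex, 0), 0, tolerance = 1e-9)
  Dconc <- 60
  got <- simulate_displacement(ex, Dconc)
  base <- (1 / 2) / (1 + 1 / 2 + 100 / 120)
  with_drug <- (1 / 2) / (1 + 1 / 2 + 100 / 120 + Dconc / 30)
  expect_equal(got, 1 - with_drug / base, tolerance = 1e-4)
  # saturation limit
  expect_gt(simulate_displacement(ex, 1e7), 0.999)
  # monotone in concentration
  d <- sapply(c(1, 10, 100, 1000), function(cc) simulate_displacement(ex, cc))
  expect_true(all(diff(d) > 0))
})

test_that("functional concentration inversion round-trips the forward model", {
  kon <- 2e-6
  nt <- ligand("NT", "neurotransmitter", kon = kon, Kd = 120)
  tracer <- ligand("T", "tracer", kon = kon, Kd = 2, concentration = 1)
  drug <- ligand("D", "drug", kon = kon, Kd = 30, concentration = 0)
  cfg <- synapse_config(list(receptor_pool(list(nt, tracer, drug), name = "post")),
                        tonic_rate_hz = 0, nt_halflife_ms = 1e12,
                        quantal_increment_nM = 0, equilibration_nM = 100,
                        transient_s = 0.5, averaging_s = 1, dt_ms = 0.02)
  truth <- 45
  obs <- simulate_displacement(tracer_experiment(cfg, "post", "T", "D"), truth)
  ex <- tracer_experiment(cfg, "post", "T", "D", observed_displacement = obs)
  est <- invert_functional_concentration(ex, tol = 1e-4)
  expect_equal(est, truth, tolerance = 5e-3)
  # a higher observed displacement inverts to a higher concentration
  obs2 <- simulate_displacement(tracer_experiment(cfg, "post", "T", "D"), 2 * truth)
  ex2 <- tracer_experiment(cfg, "post", "T", "D", observed_displacement = obs2)
  expect_gt(invert_functional_concentration(ex2, tol = 1e-4), est)
  # unreachable target reports a bracket error
  ex3 <- tracer_experiment(cfg, "post", "T", "D", observed_displacement = 0.99)
  expect_error(invert_functional_concentration(ex3, upper = 10), "not bracketed")
})

test_that("the AChE-I chain raises cholinergic activations monotonically in dose", {
  cfg <- fast_chol()
  acts <- sapply(c(0, 4, 8, 16), function(D) {
    hl <- if (D > 0) ache_dose_chain("galantamine", D)$halflife_ms else NULL
    tr <- simulate_synapse(cfg, halflife_ms = hl, record_every_ms = 100)
    tr$mean_activation$M1[["ACh"]]
  })
  expect_true(all(diff(acts) > 0))
})
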