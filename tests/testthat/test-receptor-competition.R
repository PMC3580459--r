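test_that("closed-form competitive occupancy follows the isotherm", {
  l0 <- ligand("x", "drug", kon = 1e-6, Kd = 50, concentration = 0)
  expect_equal(as.numeric(equilibrium_occupancy(l0)), 0)
  l1 <- ligand("x", "drug", kon = 1e-6, Kd = 50, concentration = 150)
  expect_equal(as.numeric(equilibrium_occupancy(l1)), 0.75)
  trio <- list(ligand("a", "neurotransmitter", kon = 1e-6, Kd = 10, concentration = 10),
               ligand("b", "drug", kon = 2e-6, Kd = 40, concentration = 40),
               ligand("c", "tracer", kon = 5e-7, Kd = 5, concentration = 10))
  occ <- equilibrium_occupancy(trio)
  expect_equal(as.numeric(occ), c(0.2, 0.2, 0.4))
  expect_equal(attr(occ, "free"), 0.2)
})

test_that("binding ODE converges to the equilibrium oracle and preserves continuity", {
  l1 <- ligand("nt", "neurotransmitter", kon = 2e-6, Kd = 100, concentration = 100)
  l2 <- ligand("dr", "drug", kon = 1e-6, Kd = 50, concentration = 100)
  pool <- receptor_pool(list(l1, l2), name = "p")
  for (i in 1:60000) pool <- integrate_binding(pool, dt = 50)
  occ <- equilibrium_occupancy(list(l1, l2))
  expect_equal(unname(pool$bound), as.numeric(occ), tolerance = 1e-6)
  expect_equal(sum(pool$bound) + pool$free, pool$R_total, tolerance = 1e-9)
  # single ligand held at its Kd occupies half the pool
  ls <- ligand("s", "neurotransmitter", kon = 2e-6, Kd = 200, concentration = 200)
  ps <- receptor_pool(ls, name = "half")
  for (i in 1:60000) ps <- integrate_binding(ps, dt = 50)
  expect_equal(unname(ps$bound), 0.5, tolerance = 1e-6)
})

test_that("with zero concentration bound ligand unbinds exponentially at kon*Kd", {
  l <- ligand("x", "drug", kon = 1e-6, Kd = 100, concentration = 0)
  pool <- receptor_pool(l, name = "p", bound = c(x = 0.8))
  dt <- 1
  n <- 5000
  for (i in seq_len(n)) pool <- integrate_binding(pool, dt = dt)
  koff <- 1e-6 * 100
  expect_equal(unname(pool$bound), 0.8 * exp(-koff * n * dt), tolerance = 1e-8)
})

test_that("integrator rejects steps that break positivity", {
  l <- ligand("x", "drug", kon = 1e-3, Kd = 1000, concentration = 0)
  pool <- receptor_pool(l, name = "p", bound = c(x = 0.9))
  expect_error(integrate_binding(pool, dt = 1e4), "dt too large")
})

test_that("release rule matches its closed forms and is strictly decreasing", {
  ph <- presynaptic_physiology(r0 = 1, rmax = 0.5, S = 7.75, B0 = 0.2)
  expect_equal(release_amount(ph$B0, ph), ph$r0)           # feedback term vanishes
  expect_equal(release_amount(0, ph), 1.5)                  # zero occupancy limit
  expect_equal(release_amount(1, ph), 0.5, tolerance = 1e-4)  # A^S >> B0^S
  A <- seq(0, 1, by = 0.01)
  r <- release_amount(A, ph)
  expect_true(all(diff(r) < 0))
  expect_true(all(r >= ph$r0 * (1 - ph$rmax) - 1e-12 &
                  r <= ph$r0 * (1 + ph$rmax) + 1e-12))
  expect_error(release_amount(1.2, ph), "\\[0, 1\\]")
})

test_that("facilitation/depression factor follows the spike-history sum", {
  ph <- presynaptic_physiology(wf = 1.1, wd = 0.42,
                               facilitation_halflife_ms = 90,
                               depression_halflife_ms = 120)
  expect_identical(facilitation_factor(numeric(0), 100, ph), 1)
  # one spike 90 ms ago: wf decayed by exactly one half-life
  f <- facilitation_factor(10, 100, ph)
  expect_equal(f, 1 + 1.1 * 0.5 - 0.42 * 2^(-90 / 120), tolerance = 1e-12)
  expect_equal(f, 1.3003, tolerance = 1e-4)
  expect_equal(facilitation_factor(-1e9, 0, ph), 1, tolerance = 1e-12)
  expect_error(facilitation_factor(c(5, 3), 10, ph), "strictly increasing")
})

test_that("synapse simulation is deterministic and decays without firing", {
  cfg <- toy_synapse(kon = 2e-5, tonic_rate_hz = 0, transient_s = 1,
                     averaging_s = 3)
  tr <- simulate_synapse(cfg)
  # free transmitter decays monotonically from the equilibration level
  expect_true(all(diff(tr$free_nM) <= 0))
  expect_lt(tr$mean_activation$post[["NT"]], 0.05)
  cfg2 <- toy_synapse()
  t1 <- simulate_synapse(cfg2)
  t2 <- simulate_synapse(cfg2)
  expect_identical(t1$free_nM, t2$free_nM)
  expect_identical(t1$occupancy, t2$occupancy)
})

test_that("tonic firing settles at the release/activation fixed point", {
  # regular train: mean cleft level from release r(A*), facilitation steady
  # state and exponential decay; A* from the binding isotherm at that mean
  cfg <- toy_synapse(tonic_rate_hz = 8, nt_halflife_ms = 5, q = 6000,
                     transient_s = 4, averaging_s = 6)
  tr <- simulate_synapse(cfg)
  ph <- cfg$presyn
  T <- 1000 / cfg$tonic_rate_hz
  fac_ss <- 1 + ph$wf / (exp(ph$kf * T) - 1) - ph$wd / (exp(ph$kd * T) - 1)
  Kd <- cfg$pools$auto$ligands$NT$Kd
  mean_c <- function(A) release_amount(A, ph) * fac_ss *
    cfg$quantal_increment_nM * (cfg$nt_halflife_ms / log(2)) / T
  fp <- stats::uniroot(function(A) mean_c(A) / (mean_c(A) + Kd) - A,
                       c(1e-6, 1 - 1e-6), tol = 1e-10)$root
  expect_equal(tr$mean_activation$auto[["NT"]], fp, tolerance = 0.03)
})

test_that("halving the integration step leaves mean activations unchanged", {
  # 8 Hz spikes fall exactly on both step grids, isolating the RK4 error
  m <- sapply(c(0.02, 0.01), function(dt) {
    cfg <- toy_synapse(tonic_rate_hz = 8, dt_ms = dt,
                       transient_s = 1, averaging_s = 2)
    tr <- simulate_synapse(cfg)
    c(tr$mean_activation$auto[["NT"]], tr$mean_activation$post[["NT"]])
  })
  expect_equal(m[, 1], m[, 2], tolerance = 1e-6)
})

test_that("postsynaptic activation is monotone in the transmitter half-life", {
  acts <- sapply(c(4, 5, 7, 10), function(hl) {
    tr <- simulate_synapse(toy_synapse(), halflife_ms = hl, record_every_ms = 100)
    tr$mean_activation$post[["NT"]]
  })
  expect_true(all(diff(acts) > 0))
})

test_that("synapse trace exports as CSV with pool.ligand occupancy columns", {
  tr <- simulate_synapse(toy_synapse(transient_s = 0.2, averaging_s = 0.3),
                         record_every_ms = 10)
  f <- tempfile(fileext = ".csv")
  df <- write_synapse_trace(tr, f)
  back <- read.csv(f)
  expect_identical(names(back), c("time_ms", "free_nM", "auto.NT", "post.NT"))
  expect_equal(nrow(back), length(tr$time_ms))
  unlink(f)
})

test_that("synapse configs round-trip through the YAML format", {
  skip_if_not_installed("yaml")
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "presyn_pool: auto",
    "tonic_rate_hz: 7",
    "nt_halflife_ms: 5",
    "quantal_increment_nM: 6400",
    "presyn: {rmax: 0.5, S: 2, B0: 0.5, wf: 0.3, wd: 0.2}",
    "pools:",
    "  auto:",
    "    ACh: {role: neurotransmitter, kon: 2.0e-6, Kd_nM: 320}",
    "  post:",
    "    ACh: {role: neurotransmitter, kon: 2.0e-6, Kd_nM: 304}",
    "    tracer: {role: tracer, kon: 2.0e-6, Kd_nM: 2, concentration_nM: 1}"),
    f)
  cfg <- read_synapse_config(f)
  expect_s3_class(cfg, "adwm_synapse_config")
  expect_identical(cfg$presyn_pool, "auto")
  expect_equal(cfg$tonic_rate_hz, 7)
  expect_equal(cfg$pools$post$ligands$tracer$concentration, 1)
  expect_equal(cfg$pools$post$ligands$ACh$Kd, 304)
  expect_equal(cfg$presyn$S, 2)
  unlink(f)
})
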