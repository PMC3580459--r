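test_that("gating functions hit their closed-form anchors", {
  # removable singularity of the fast-sodium activation rate
  naf <- gating_rates("Naf", -28)
  a_lim <- 0.2816 * 9.3
  b <- 0.2464 * (-27) / (-1 + exp(-27 / 6))
  expect_equal(naf$act$x_inf, a_lim / (a_lim + b), tolerance = 1e-4)
  # slowly inactivating K+ activation midpoint
  ks <- gating_rates("Ks", -34)
  expect_equal(ks$act$x_inf, 0.5)
  expect_equal(ks$act$tau_ms, 6)
})

test_that("all gates stay in [0,1] with positive time constants over the voltage grid", {
  V <- seq(-120, 60, by = 1)
  for (ch in c("Naf", "Nap", "Kdr", "Ks", "Hva", "KCa", "int_Naf", "int_Kdr")) {
    gr <- gating_rates(ch, V)
    for (gate in gr) {
      expect_true(all(gate$x_inf >= 0 & gate$x_inf <= 1), label = ch)
      expect_true(all(gate$tau_ms > 0), label = ch)
    }
  }
  # KCa is evaluated at the calcium-shifted potential; check a high-Ca state too
  gr <- gating_rates("KCa", V, Cai = 1e-5)
  expect_true(all(gr$act$x_inf >= 0 & gr$act$x_inf <= 1 & gr$act$tau_ms > 0))
})

test_that("dual-exponential synapse peaks where the derivative vanishes", {
  expect_equal(synaptic_conductance(1, 2, 10, 0), 0)
  tstar <- 2 * 10 / (10 - 2) * log(10 / 2)
  expect_equal(tstar, 2.5 * log(5), tolerance = 1e-12)
  tt <- seq(0, 60, by = 0.001)
  g <- synaptic_conductance(1, 2, 10, tt)
  expect_equal(tt[which.max(g)], tstar, tolerance = 1e-3)
  expect_lt(synaptic_conductance(1, 2, 10, 1000), 1e-12)
})

test_that("magnesium block has the right limits and midpoint value", {
  expect_equal(mg_block(c(-80, 0, 40), mg_mM = 0), c(1, 1, 1))
  expect_lt(mg_block(-200, 1), 1e-4)
  expect_equal(mg_block(0, 1), 1 / (1 + 1 / 3.57), tolerance = 1e-12)
  expect_equal(mg_block(0, 1), 0.781, tolerance = 1e-3)
})

test_that("after-depolarization is an alpha function peaking at tau", {
  expect_equal(adp_current(0, 2, 100), 0)
  expect_equal(adp_current(100, 2, 100), 2)
  expect_equal(adp_current(500, 2, 100), 2 * 5 * exp(-4), tolerance = 1e-12)
  expect_equal(adp_current(500, 1, 100), 0.0916, tolerance = 1e-3)
})

test_that("network construction obeys the population and connectivity rules", {
  net <- build_network(seed = 7)
  nn <- net$neurons
  expect_equal(sum(nn$type == "pyr"), 80)
  expect_equal(sum(nn$type == "int"), 40)
  expect_equal(sum(nn$stimulated), 40)
  # exactly 40% of interneurons have no synapse onto any pyramidal cell
  int_ids <- nn$id[nn$type == "int"]
  pyr_ids <- nn$id[nn$type == "pyr"]
  onto_pyr <- unique(net$synapses$pre[net$synapses$post %in% pyr_ids &
                                      net$synapses$pre %in% int_ids])
  expect_equal(length(setdiff(int_ids, onto_pyr)), 16)
  expect_setequal(onto_pyr, nn$id[nn$projecting])
  # all-to-all pyramidal recurrence including self-connections
  ee <- net$synapses[net$synapses$class == "ee" & net$synapses$kind == "ampa", ]
  expect_equal(nrow(ee), 80 * 80)
  expect_error(build_network(cfg = network_config(frac_int_projecting = 1.4)),
               "config error")
})

test_that("an isolated leak-only compartment relaxes exponentially to its reversal", {
  # white-box check of the integrator against the analytic membrane equation
  gl <- 0.05; el <- -70; area <- 2e-5
  comp <- list(area = area, gnaf = 0, gnap = 0, ghva = 0, gkdr = 0, gks = 0,
               gkca = 0, gl = gl, el = el, kdr_scale = 1, type = 0L,
               neuron = 0L)
  comp <- lapply(comp, function(x) if (is.numeric(x)) x else x)
  # depolarize with a current step, then watch the relaxation
  amp <- 0.02  # nA
  res <- adwm:::cpp_run_network(
    comp, list(a = integer(0), b = integer(0), g_uS = numeric(0)),
    0L, list(pre = integer(0), comp = integer(0), kind = integer(0),
             g_uS = numeric(0)),
    list(tau_rise = c(0.5, 2, 0.5), tau_decay = c(2.4, 130, 8), e_exc = 0,
         e_gaba_pyr = -70, e_gaba_int = -75, mg_mM = 1, e_na = 55, e_k = -80,
         e_ca = 120, spike_threshold = -20, refractory_ms = 2),
    list(step = integer(0), comp = integer(0), g_uS = 0, w = numeric(0)),
    list(comps = 0L, amp_nA = amp, t0_ms = 0, dur_ms = 200),
    list(comps = integer(0), amp_nA = 0, tau_ms = 1, t0_ms = 0),
    500, 0.025, 1, list(k_ca = 0, tau_ca = 250, ca0 = 5e-8, k_ca2 = 0, tau_ca2 = 8000),
    0L, 0.5)
  v <- res$voltage$v[, 1]
  t <- res$voltage$time_ms
  # steady state under current: el + I/g (density units)
  v_on <- el + (amp * 1e-3 / area) / gl
  expect_equal(v[t == 150], v_on, tolerance = 1e-3)
  # relaxation after stimulus off: time constant C/gl = 20 ms
  sel <- t >= 200
  pred <- el + (v[t == 200] - el) * exp(-(t[sel] - 200) * gl)
  expect_equal(v[sel], pred, tolerance = 1e-3)
})

test_that("fixed seed gives a bit-identical raster", {
  net <- build_network(seed = 3)
  s1 <- run_simulation(net, duration_s = 3, seed = 11)
  s2 <- run_simulation(net, duration_s = 3, seed = 11)
  expect_identical(s1$raster, s2$raster)
  s3 <- run_simulation(net, duration_s = 3, seed = 12)
  expect_false(identical(s1$raster, s3$raster))
})

test_that("halving the step preserves spike counts of a noise-free run", {
  # isolated cells (synapses and noise silenced): the full recurrent
  # network is chaotic, so only the single-cell limit isolates integrator
  # error.  The exponential-Euler update has a first-order period error
  # (~2% of an interspike interval per step size), so within a sustained
  # train absolute spike times drift by a few ms while counts and onsets
  # converge; the span readout bins at 200 ms, two orders coarser.
  spikes <- lapply(c(0.025, 0.0125), function(dt) {
    cfg <- network_config(noise_rate_hz = 0, noise_int_rate_hz = 0,
                          dt_ms = dt, stim_t0_ms = 300,
                          stim_dur_ms = 700, stim_amp_nA = 0.5)
    net <- build_network(1, cfg)
    net$synapses$gbar_uS <- 0
    run_simulation(net, duration_s = 1.3, seed = 1)$raster
  })
  expect_gt(nrow(spikes[[1]]), 0)
  expect_equal(nrow(spikes[[1]]), nrow(spikes[[2]]))
  # onset of firing converges below half a millisecond
  f1 <- tapply(spikes[[1]]$time_ms, spikes[[1]]$neuron, min)
  f2 <- tapply(spikes[[2]]$time_ms, spikes[[2]]$neuron, min)
  expect_true(all(abs(f1 - f2[names(f1)]) < 0.5))
})

test_that("silencing the interneurons disinhibits the pyramidal population", {
  net <- build_network(seed = 2)
  sim <- run_simulation(net, duration_s = 3, seed = 5)
  silenced <- net
  silenced$synapses <- silenced$synapses[silenced$synapses$kind != "gaba", ]
  sim2 <- run_simulation(silenced, duration_s = 3, seed = 5)
  pyr_spikes <- function(s) sum(s$raster$neuron <= 80)
  expect_gt(pyr_spikes(sim2), pyr_spikes(sim))
})

test_that("without a stimulus the attractor never ignites", {
  net <- build_network(seed = 4)
  spans <- sapply(1:3, function(s) {
    sim <- run_simulation(net, duration_s = 3, seed = s, stim = list(amp_nA = 0))
    working_memory_span(sim)
  })
  expect_true(all(spans == 0))
})

test_that("raster export writes TSV plus provenance sidecar", {
  net <- build_network(seed = 1)
  sim <- run_simulation(net, duration_s = 2.5, seed = 1)
  f <- tempfile(fileext = ".tsv")
  write_raster(sim, f)
  back <- read.delim(f)
  expect_identical(names(back), c("time_ms", "neuron"))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$seed, 1)
  unlink(c(f, paste0(f, ".json")))
})
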