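test_that("pathology accumulates linearly from the stage baselines", {
  pr <- pathology_presets()
  expect_equal(pr$ad_baseline$synapse_loss, 0.05)
  expect_equal(pr$ad_baseline$neuron_loss, 0.05)
  expect_equal(pr$mci$synapse_loss, 0.03)
  expect_equal(pr$mci$neuron_loss, 0.04)
  st <- progress_pathology(0)
  expect_equal(c(st$synapse_loss, st$neuron_loss), c(0.05, 0.05))
  st52 <- progress_pathology(52)
  expect_equal(st52$neuron_loss, 0.05 + 0.0025 * 52)   # 18% at one year
  expect_equal(st52$synapse_loss, 0.05 + 0.0004 * 52, tolerance = 1e-12)
  expect_error(progress_pathology(-1), "non-negative")
})

test_that("lesioning preserves the stimulated/unstimulated balance", {
  net <- build_network(seed = 2)
  same <- apply_lesion(net, pathology_state(), seed = 9)
  expect_identical(same$neurons, net$neurons)
  expect_identical(same$synapses, net$synapses)
  les <- apply_lesion(net, pathology_state(neuron_loss = 0.05), seed = 9)
  nn <- les$neurons
  expect_equal(sum(!nn$alive), 4)                      # 5% of 80
  expect_equal(sum(!nn$alive & nn$stimulated), 2)
  expect_equal(sum(!nn$alive & !nn$stimulated & nn$type == "pyr"), 2)
  expect_true(all(nn$alive[nn$type == "int"]))         # interneurons spared
  # every surviving synapse references alive neurons
  alive <- nn$id[nn$alive]
  expect_true(all(les$synapses$pre %in% alive & les$synapses$post %in% alive))
})

test_that("synapse deletion removes the stated fraction of e-e and e-i pairs", {
  net <- build_network(seed = 3)
  frac <- 0.10
  les <- apply_lesion(net, pathology_state(synapse_loss = frac), seed = 5)
  for (cl in c("ee", "ei")) {
    n0 <- nrow(unique(net$synapses[net$synapses$class == cl, c("pre", "post")]))
    n1 <- nrow(unique(les$synapses[les$synapses$class == cl, c("pre", "post")]))
    expect_equal(n1, round((1 - frac) * n0))
    # AMPA and NMDA of one connection are removed together
    counts <- table(paste(les$synapses$pre, les$synapses$post,
                          les$synapses$class)[les$synapses$class == cl])
    expect_true(all(counts == 2))
  }
})

test_that("ApoE4 adds allele-dependent synapse loss and homozygous ACh deficit", {
  mci <- pathology_presets()$mci
  expect_identical(apply_apoe(mci, 0), mci)
  one <- apply_apoe(mci, 1)
  expect_equal(one$synapse_loss, 0.06)               # 3% + 3%
  expect_equal(one$ach_deficit, mci$ach_deficit)
  st <- pathology_state(synapse_loss = 0.07, ach_deficit = 0.30)
  two <- apply_apoe(st, 2)
  expect_equal(two$synapse_loss, 0.12)               # +5 exactly
  expect_equal(two$ach_deficit, 1 - 0.7 * 0.9)
  expect_error(apply_apoe(mci, 3), "0, 1 or 2")
})

test_that("memantine scales only the targeted NMDA conductances", {
  net <- build_network(seed = 1)
  ident <- apply_memantine(net, 0, 0)
  expect_identical(ident, net)
  out <- apply_memantine(net)
  s0 <- net$synapses; s1 <- out$synapses
  ee <- s0$kind == "nmda" & s0$class == "ee"
  ei <- s0$kind == "nmda" & s0$class == "ei"
  expect_equal(s1$gbar_uS[ee], s0$gbar_uS[ee] * 0.995)
  expect_equal(s1$gbar_uS[ei], s0$gbar_uS[ei] * 0.99)
  expect_equal(s1$gbar_uS[!(ee | ei)], s0$gbar_uS[!(ee | ei)])
  # the subunit-nonselective hypothetical compound
  eq <- apply_memantine(net, 0.01, 0.01)
  expect_equal(eq$synapses$gbar_uS[ee], s0$gbar_uS[ee] * 0.99)
  expect_equal(eq$synapses$gbar_uS[ei], s0$gbar_uS[ei] * 0.99)
})

test_that("memantine at zero dose leaves rasters bit-identical", {
  net <- build_network(seed = 4)
  a <- run_simulation(net, duration_s = 3, seed = 8)
  b <- run_simulation(apply_memantine(net, 0, 0), duration_s = 3, seed = 8)
  expect_identical(a$raster, b$raster)
})

test_that("condition builder composes pathology, placebo and dose chains", {
  pl <- build_condition("placebo", week = 12)
  expect_equal(pl$state$da_placebo, 0.075)
  expect_equal(pl$state$week, 12)
  expect_equal(pl$state$ach_deficit, 0.175)
  don <- build_condition("donepezil", week = 26, dose_mg = 10)
  ch <- ache_dose_chain("donepezil", 10)
  expect_equal(ch$inhibition, 0.4)
  expect_equal(ch$halflife_ms, 25 / 3, tolerance = 1e-12)
  expect_equal(don$intervention$mechanism, "AChE-I")
  sb <- build_condition("SB-742457", week = 26, dose_mg = 35)
  expect_equal(sb$intervention$mechanism, "5HT6-antagonist")
  act <- condition_activations(sb)
  expect_equal(unname(act$treated["5HT6"]), 0.031)
  expect_equal(unname(act$control["5HT6"]), 0.406)
  expect_error(build_condition("aspirin", week = 12), "known")
})

test_that("condition activations track the cholinergic state", {
  # pure cholinergic deficit lowers all cholinergic activations
  cnd <- build_condition("placebo", week = 0)
  cnd$state$da_placebo <- 0
  act <- condition_activations(cnd)
  for (r in c("M1", "M2", "a7", "a4b2"))
    expect_lt(act$treated[[r]], act$control[[r]])
  # an AChE-I partially restores them
  don <- build_condition("donepezil", week = 0, dose_mg = 10)
  don$state$da_placebo <- 0
  act2 <- condition_activations(don)
  for (r in c("M1", "M2", "a7", "a4b2"))
    expect_gt(act2$treated[[r]], act$treated[[r]])
})
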