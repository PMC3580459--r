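# Shared builders for the test suite.  Everything is generated in code; the
# only file fixture is the clinical CSV shipped in inst/extdata.

# a minimal one-pool synapse for fast receptor-competition tests
toy_synapse <- function(Kd = 100, kon = 2e-6, tonic_rate_hz = 7,
                        nt_halflife_ms = 5, q = 5000, dt_ms = 0.02,
                        transient_s = 2, averaging_s = 3, ...) {
  nt <- ligand("NT", "neurotransmitter", kon = kon, Kd = Kd)
  synapse_config(list(receptor_pool(nt, name = "auto"),
                      receptor_pool(nt, name = "post")),
                 presyn_pool = "auto",
                 presyn = presynaptic_physiology(rmax = 0.5, S = 2, B0 = 0.5,
                                                 wf = 0.3, wd = 0.2),
                 tonic_rate_hz = tonic_rate_hz,
                 nt_halflife_ms = nt_halflife_ms,
                 quantal_increment_nM = q,
                 transient_s = transient_s, averaging_s = averaging_s,
                 dt_ms = dt_ms, ...)
}

# trimmed cholinergic preset for pipeline tests (periodic steady state is
# reached well before the averaging window)
fast_chol <- function() make_cholinergic_synapse(dt_ms = 0.02,
                                                 transient_s = 2,
                                                 averaging_s = 3)

# a small raster data frame builder
toy_raster <- function(times_ms, neurons) {
  data.frame(time_ms = times_ms, neuron = neurons)
}
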