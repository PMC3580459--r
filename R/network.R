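#' Cortical network configuration
#'
#' Parameter set for the prefrontal working-memory network: population
#' sizes and connectivity fractions, compartment geometry and channel
#' densities (per the compartment parameter tables), synaptic kinetics and
#' maximal conductances, background noise, the memory stimulus and the
#' after-depolarization.  All values the published tables do not fix are
#' exposed here; their defaults are the package's calibration, chosen so
#' the healthy network holds a stimulus-evoked attractor with a working
#' memory span above 9 s on average (typical range 4-10 s).
#'
#' @param ... Named overrides of any default listed in the function body.
#' @return List of class \code{adwm_network_config}.
#' @export
network_config <- function(...) {
  cfg <- list(
    n_pyr = 80L, n_int = 40L, frac_stimulated = 0.5,
    frac_int_projecting = 0.6,   # 60% of interneurons synapse onto pyramids
    contacts_per_pair = 1L,      # multiple-contact multiplier
    autapses = TRUE,             # pyramidal self-connections
    # synaptic kinetics: AMPA, NMDA, GABA-A (ms)
    tau_rise = c(ampa = 0.5, nmda = 2, gaba = 0.5),
    tau_decay = c(ampa = 2.4, nmda = 130, gaba = 8),
    e_exc = 0, e_gaba_pyr = -70, e_gaba_int = -75,
    mg_mM = 1,
    # maximal conductances per synapse (uS), calibrated
    g_ampa_ee = 1.80e-3, g_nmda_ee = 0.55e-3,
    g_ampa_ei = 0.2e-3, g_nmda_ei = 0.12e-3,
    g_gaba_ip = 4.0e-3, g_gaba_ii = 2.0e-3,
    # membrane passive properties
    gl_pyr = 0.1, gl_int = 0.1,    # mS/cm^2
    el_pyr = -75, el_int = -70, e_na = 55, e_k = -80, e_ca = 120,
    ra_ohm_cm = 150,
    # calcium pool (molar units)
    k_ca = 2.5e-8, tau_ca = 250, ca0 = 5e-8,
    k_ca2 = 7e-10, tau_ca2 = 8000,
    # background noise: independent Poisson AMPA events onto every neuron;
    # interneurons get their own stronger stream so the inhibitory tone is
    # set by the network's surround, not only by local pyramidal drive
    noise_rate_hz = 250, noise_g_uS = 1.2e-3,
    noise_int_rate_hz = 1000, noise_int_g_uS = 1.5e-3,
    # memory stimulus: current into the somata of the stimulated pyramids
    stim_t0_ms = 2000, stim_dur_ms = 200, stim_amp_nA = 1.0,
    # mGluR5 after-depolarization (alpha function) on stimulated pyramids
    adp_amp_nA = 0.23, adp_tau_ms = 2800,
    # integration
    dt_ms = 0.025, delay_ms = 1,
    spike_threshold = -20, refractory_ms = 2)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "adwm_network_config"
  cfg
}

# Compartment geometry and channel densities (lengths/diameters um,
# conductances mS/cm^2).  Pyramidal compartments are chained
# apical-distal -- proximal -- soma -- basal; interneurons dendrite -- soma.
.adwm_compartments <- function() {
  data.frame(
    cell = c(rep("pyr", 4), rep("int", 2)),
    role = c("apical", "proximal", "soma", "basal", "dendrite", "soma"),
    L = c(400, 400, 86.3, 150, 150, 15),
    diam = c(2.6, 2.6, 6.14, 16, 10, 15),
    gnaf = c(28, 28, 86, 28, 20, 100),
    gnap = c(0, 1.0, 2.2, 1.0, 0, 0),
    ghva = c(0.255, 0.63, 0.306, 0.63, 0, 0),
    gkdr = c(9.2, 9.2, 33.8, 9.2, 8, 40),
    gks = c(0.18, 0.18, 0.105, 0.18, 0, 0),
    gkca = c(2.2, 3.8, 2.2, 3.8, 0, 0),
    stringsAsFactors = FALSE)
}

#' Build the cortical network graph
#'
#' Constructs the 80-pyramid / 40-interneuron network: all pyramidal cells
#' form a recurrent glutamatergic network (AMPA + NMDA) and synapse onto
#' every interneuron; a seeded random 60\% subset of the interneurons
#' projects GABA-A synapses onto all pyramidal cells, while the remaining
#' 40\% contact only other interneurons; all interneurons participate in
#' the inhibitory recurrent network.  Half of the pyramidal cells (the
#' attractor population) receive the memory stimulus.
#'
#' @param seed Integer seed; fully determines the graph (which interneurons
#'   project, which pyramids are stimulated).
#' @param cfg A \code{\link{network_config}}.
#' @return Object of class \code{adwm_network}: \code{neurons} (data frame:
#'   \code{id}, \code{type}, \code{stimulated}, \code{projecting},
#'   \code{alive}), \code{synapses} (data frame: \code{pre}, \code{post},
#'   \code{kind}, \code{class}, \code{gbar_uS}, \code{modulation_scale}),
#'   \code{config}, \code{seed}, \code{kdr_scale}.
#' @export
build_network <- function(seed = 1L, cfg = network_config()) {
  stopifnot(inherits(cfg, "adwm_network_config"))
  n_pyr <- cfg$n_pyr; n_int <- cfg$n_int
  if (n_pyr < 2 || n_int < 1) stop("population counts too small")
  if (cfg$frac_int_projecting < 0 || cfg$frac_int_projecting > 1 ||
      cfg$frac_stimulated < 0 || cfg$frac_stimulated > 1)
    stop("config error: fractions must lie in [0, 1]")
  set.seed(seed)
  n_stim <- round(cfg$frac_stimulated * n_pyr)
  n_proj <- round(cfg$frac_int_projecting * n_int)
  pyr_ids <- seq_len(n_pyr)
  int_ids <- n_pyr + seq_len(n_int)
  stim_ids <- sort(sample(pyr_ids, n_stim))
  proj_ids <- sort(sample(int_ids, n_proj))
  neurons <- data.frame(
    id = c(pyr_ids, int_ids),
    type = rep(c("pyr", "int"), c(n_pyr, n_int)),
    stimulated = c(pyr_ids %in% stim_ids, rep(FALSE, n_int)),
    projecting = c(rep(FALSE, n_pyr), int_ids %in% proj_ids),
    alive = TRUE, stringsAsFactors = FALSE)

  pair <- function(pre, post, self_ok) {
    g <- expand.grid(pre = pre, post = post, KEEP.OUT.ATTRS = FALSE)
    if (!self_ok) g <- g[g$pre != g$post, ]
    g
  }
  ee <- pair(pyr_ids, pyr_ids, cfg$autapses)
  ei <- pair(pyr_ids, int_ids, TRUE)
  ip <- pair(proj_ids, pyr_ids, TRUE)
  ii <- pair(int_ids, int_ids, FALSE)
  syn <- rbind(
    data.frame(ee, kind = "ampa", class = "ee", gbar_uS = cfg$g_ampa_ee),
    data.frame(ee, kind = "nmda", class = "ee", gbar_uS = cfg$g_nmda_ee),
    data.frame(ei, kind = "ampa", class = "ei", gbar_uS = cfg$g_ampa_ei),
    data.frame(ei, kind = "nmda", class = "ei", gbar_uS = cfg$g_nmda_ei),
    data.frame(ip, kind = "gaba", class = "ip", gbar_uS = cfg$g_gaba_ip),
    data.frame(ii, kind = "gaba", class = "ii", gbar_uS = cfg$g_gaba_ii))
  if (cfg$contacts_per_pair > 1L)
    syn$gbar_uS <- syn$gbar_uS * cfg$contacts_per_pair
  syn$modulation_scale <- 1
  rownames(syn) <- NULL
  structure(list(neurons = neurons, synapses = syn, config = cfg,
                 seed = as.integer(seed), kdr_scale = 1),
            class = "adwm_network")
}

#' @export
print.adwm_network <- function(x, ...) {
  nn <- x$neurons
  cat(sprintf(paste0("<network> %d pyramidal (%d stimulated) + %d interneurons",
                     " (%d projecting), %d alive\n  %d synapses, seed %d\n"),
              sum(nn$type == "pyr"), sum(nn$stimulated), sum(nn$type == "int"),
              sum(nn$projecting), sum(nn$alive), nrow(x$synapses), x$seed))
  if (x$kdr_scale != 1)
    cat(sprintf("  pyramidal Kdr scale %.4g\n", x$kdr_scale))
  invisible(x)
}

## Internal: flatten an adwm_network into the C++ argument lists.
.network_cpp_args <- function(net) {
  cfg <- net$config
  nn <- net$neurons[net$neurons$alive, ]
  comp_def <- .adwm_compartments()
  rows <- lapply(seq_len(nrow(nn)), function(i) {
    def <- comp_def[comp_def$cell == nn$type[i], ]
    def$neuron <- nn$id[i]
    def
  })
  comps <- do.call(rbind, rows)
  comps$area_cm2 <- pi * comps$L * comps$diam * 1e-8
  comps$type_i <- ifelse(comps$cell == "pyr", 0L, 1L)
  comps$gl <- ifelse(comps$cell == "pyr", cfg$gl_pyr, cfg$gl_int)
  comps$el <- ifelse(comps$cell == "pyr", cfg$el_pyr, cfg$el_int)
  comps$kdr_scale <- ifelse(comps$cell == "pyr", net$kdr_scale, 1)
  comps$idx0 <- seq_len(nrow(comps)) - 1L

  # axial edges within each neuron (chain in table order)
  g_half <- function(L, d) {
    # half-compartment axial resistance (ohm): (4 Ra / pi) * (L/2) / d^2
    (4 * cfg$ra_ohm_cm / pi) * (L * 1e-4 / 2) / (d * 1e-4)^2
  }
  ax_a <- integer(0); ax_b <- integer(0); ax_g <- numeric(0)
  for (id in unique(comps$neuron)) {
    sel <- which(comps$neuron == id)
    for (k in seq_len(length(sel) - 1)) {
      i <- sel[k]; j <- sel[k + 1]
      r <- g_half(comps$L[i], comps$diam[i]) + g_half(comps$L[j], comps$diam[j])
      ax_a <- c(ax_a, comps$idx0[i]); ax_b <- c(ax_b, comps$idx0[j])
      ax_g <- c(ax_g, 1 / r * 1e6)  # S -> uS
    }
  }

  # neuron id -> consecutive 0-based index among alive neurons
  id2i <- stats::setNames(seq_len(nrow(nn)) - 1L, nn$id)
  soma <- vapply(nn$id, function(id)
    comps$idx0[comps$neuron == id & comps$role == "soma"], integer(1))

  # synaptic target compartments: excitatory on the proximal dendrite of
  # pyramids / the dendrite of interneurons; GABA-A on the soma
  tgt_comp <- function(post, kind) {
    role <- ifelse(kind == "gaba", "soma",
                   ifelse(post <= cfg$n_pyr, "proximal", "dendrite"))
    vapply(seq_along(post), function(k)
      comps$idx0[comps$neuron == post[k] & comps$role == role[k]], integer(1))
  }
  syn <- net$synapses
  keep <- syn$pre %in% nn$id & syn$post %in% nn$id
  syn <- syn[keep, ]
  kind_i <- match(syn$kind, c("ampa", "nmda", "gaba")) - 1L
  list(
    comp = list(area = comps$area_cm2, gnaf = comps$gnaf, gnap = comps$gnap,
                ghva = comps$ghva, gkdr = comps$gkdr, gks = comps$gks,
                gkca = comps$gkca, gl = comps$gl, el = comps$el,
                kdr_scale = comps$kdr_scale, type = comps$type_i,
                neuron = unname(id2i[as.character(comps$neuron)])),
    axial = list(a = ax_a, b = ax_b, g_uS = ax_g),
    soma = unname(soma),
    syn = list(pre = unname(id2i[as.character(syn$pre)]),
               comp = tgt_comp(syn$post, syn$kind), kind = kind_i,
               g_uS = syn$gbar_uS * syn$modulation_scale),
    neurons = nn, comps = comps)
}

#' Run a network simulation
#'
#' Integrates the full network and returns the spike raster.  All
#' randomness (background noise event times) is drawn in R under the given
#' seed before the deterministic C++ integration, so a fixed
#' (network, seed) pair gives a bit-identical raster.
#'
#' @param net An \code{\link{build_network}} result (possibly lesioned /
#'   modulated).
#' @param duration_s Simulated time in seconds (must cover the stimulus).
#' @param seed Integer seed for the background noise.
#' @param stim Stimulus override list with any of \code{t0_ms},
#'   \code{dur_ms}, \code{amp_nA}; \code{amp_nA = 0} disables the stimulus
#'   (and the after-depolarization it triggers).
#' @param record_v Optional data frame request for voltage traces:
#'   \code{neuron} ids (somata are recorded), or \code{NULL}.
#' @param record_every_ms Voltage trace resolution.
#' @return Object of class \code{adwm_sim_result}: \code{raster} (data
#'   frame \code{time_ms}, \code{neuron}, sorted by time), \code{duration_s},
#'   \code{seed}, \code{stimulated} (ids of alive stimulated cells),
#'   \code{voltage} (optional).
#' @export
run_simulation <- function(net, duration_s = 15, seed = 1L, stim = list(),
                           record_v = NULL, record_every_ms = 1) {
  stopifnot(inherits(net, "adwm_network"))
  cfg <- net$config
  t0 <- stim$t0_ms %||% cfg$stim_t0_ms
  dur <- stim$dur_ms %||% cfg$stim_dur_ms
  amp <- stim$amp_nA %||% cfg$stim_amp_nA
  duration_ms <- duration_s * 1000
  if (amp != 0 && duration_ms < t0) stop("duration must cover the stimulus time")
  args <- .network_cpp_args(net)
  nn <- args$neurons
  n_alive <- nrow(nn)

  # background noise: per-neuron Poisson trains onto the dendritic target
  set.seed(seed)
  tgt_role <- ifelse(nn$type == "pyr", "proximal", "dendrite")
  tgt <- vapply(seq_len(n_alive), function(k)
    args$comps$idx0[args$comps$neuron == nn$id[k] &
                    args$comps$role == tgt_role[k]], integer(1))
  rate <- ifelse(nn$type == "pyr", cfg$noise_rate_hz, cfg$noise_int_rate_hz)
  # interneuron events are weighted relative to the pyramidal amplitude and
  # folded into one event stream (the core applies a single amplitude)
  wrel <- ifelse(nn$type == "pyr", 1, cfg$noise_int_g_uS / cfg$noise_g_uS)
  ev_t <- vector("list", n_alive); ev_w <- vector("list", n_alive)
  for (k in seq_len(n_alive)) {
    if (rate[k] <= 0) { ev_t[[k]] <- numeric(0); ev_w[[k]] <- numeric(0); next }
    mean_gap <- 1000 / rate[k]
    n_exp <- ceiling(duration_ms / mean_gap * 1.5) + 20
    tt <- cumsum(stats::rexp(n_exp, rate = 1 / mean_gap))
    while (tt[length(tt)] < duration_ms)
      tt <- c(tt, tt[length(tt)] + cumsum(stats::rexp(n_exp, 1 / mean_gap)))
    ev_t[[k]] <- tt[tt < duration_ms]
    ev_w[[k]] <- rep(wrel[k], length(ev_t[[k]]))
  }
  all_t <- unlist(ev_t)
  all_c <- rep(tgt, lengths(ev_t))
  all_w <- unlist(ev_w)
  o <- order(all_t)
  noise_step <- as.integer(round(all_t[o] / cfg$dt_ms))
  noise_comp <- all_c[o]
  noise_w <- all_w[o]

  stim_ids <- nn$id[nn$stimulated]
  stim_comps <- args$soma[match(stim_ids, nn$id)]

  # the after-depolarization is mGluR5-dependent, i.e. driven by synaptic
  # glutamate: its amplitude scales with the surviving (and modulated)
  # recurrent glutamatergic drive onto the stimulated population relative
  # to the intact network
  adp_scale <- 1
  if (length(stim_ids)) {
    syn <- net$synapses
    ee <- syn$class == "ee" & syn$post %in% stim_ids
    drive <- sum(syn$gbar_uS[ee] * syn$modulation_scale[ee]) / length(stim_ids)
    ref <- cfg$n_pyr * (cfg$g_ampa_ee + cfg$g_nmda_ee) * cfg$contacts_per_pair
    adp_scale <- drive / ref
  }
  res <- cpp_run_network(
    args$comp, args$axial, args$soma, args$syn,
    list(tau_rise = unname(cfg$tau_rise), tau_decay = unname(cfg$tau_decay),
         e_exc = cfg$e_exc, e_gaba_pyr = cfg$e_gaba_pyr,
         e_gaba_int = cfg$e_gaba_int, mg_mM = cfg$mg_mM,
         e_na = cfg$e_na, e_k = cfg$e_k, e_ca = cfg$e_ca,
         spike_threshold = cfg$spike_threshold,
         refractory_ms = cfg$refractory_ms),
    list(step = noise_step, comp = noise_comp, g_uS = cfg$noise_g_uS,
         w = noise_w),
    list(comps = if (amp != 0) stim_comps else integer(0),
         amp_nA = amp, t0_ms = t0, dur_ms = dur),
    list(comps = if (amp != 0 && cfg$adp_amp_nA != 0) stim_comps else integer(0),
         amp_nA = cfg$adp_amp_nA * adp_scale, tau_ms = cfg$adp_tau_ms,
         t0_ms = t0),
    duration_ms, cfg$dt_ms, cfg$delay_ms,
    list(k_ca = cfg$k_ca, tau_ca = cfg$tau_ca, ca0 = cfg$ca0,
         k_ca2 = cfg$k_ca2, tau_ca2 = cfg$tau_ca2),
    if (is.null(record_v)) integer(0) else
      args$soma[match(record_v, nn$id)],
    record_every_ms)

  raster <- data.frame(time_ms = res$spike_time_ms,
                       neuron = nn$id[res$spike_neuron])
  raster <- raster[order(raster$time_ms, raster$neuron), ]
  rownames(raster) <- NULL
  out <- list(raster = raster, duration_s = duration_s, seed = as.integer(seed),
              stimulated = stim_ids, stim_t0_ms = t0,
              voltage = res$voltage)
  if (!is.null(res$voltage) && !is.null(record_v))
    colnames(out$voltage$v) <- as.character(record_v)
  class(out) <- "adwm_sim_result"
  out
}

#' @export
print.adwm_sim_result <- function(x, ...) {
  cat(sprintf("<simulation> %g s, %d spikes from %d neurons (seed %d)\n",
              x$duration_s, nrow(x$raster), length(unique(x$raster$neuron)),
              x$seed))
  invisible(x)
}

#' Write a spike raster as TSV
#'
#' Two columns (\code{time_ms}, \code{neuron_id}) plus a JSON sidecar with
#' the seed and population sizes for provenance.
#'
#' @param sim An \code{adwm_sim_result}.
#' @param file Path of the TSV; the sidecar is \code{<file>.json}.
#' @return \code{file}, invisibly.
#' @export
write_raster <- function(sim, file) {
  stopifnot(inherits(sim, "adwm_sim_result"))
  utils::write.table(sim$raster, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  side <- list(seed = sim$seed, duration_s = sim$duration_s,
               n_stimulated = length(sim$stimulated),
               stim_t0_ms = sim$stim_t0_ms)
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
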