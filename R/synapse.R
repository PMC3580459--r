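#' Synapse simulation configuration
#'
#' Bundles everything needed to run the receptor-competition synapse: the
#' receptor pools with their competing ligands, the presynaptic release
#' physiology, the firing regime and the free-transmitter decay law.
#'
#' The simulation protocol has three phases: (1) all pools are equilibrated
#' analytically at a constant free transmitter of
#' \code{equilibration_nM}; (2) a transient of \code{transient_s} seconds of
#' tonic firing lets release, decay and binding settle; (3) a further
#' \code{averaging_s} seconds over which mean activations are accumulated.
#' Free transmitter decays exponentially with half-life
#' \code{nt_halflife_ms}; each presynaptic spike adds
#' \code{release * quantal_increment_nM} to the cleft.
#'
#' @param pools List of \code{\link{receptor_pool}} objects.  The
#'   neurotransmitter ligand (role \code{"neurotransmitter"}) in each pool is
#'   driven by the simulated free-transmitter time course; all other ligands
#'   keep their constant concentrations.
#' @param presyn_pool Name of the pool acting as the presynaptic
#'   autoreceptor (its transmitter occupancy feeds back on release), or
#'   \code{NULL} for no autoregulation.
#' @param presyn A \code{\link{presynaptic_physiology}} object.
#' @param tonic_rate_hz Tonic firing rate of the presynaptic terminal (Hz);
#'   firing is a deterministic regular train.
#' @param nt_halflife_ms Free-transmitter decay half-life (ms).
#' @param quantal_increment_nM Cleft concentration added per unit release
#'   (nM); the release rule is normalised to \code{r0 = 1} so this is the
#'   concentration of one baseline release event.
#' @param equilibration_nM Constant free transmitter for the analytic
#'   equilibration phase (nM).
#' @param transient_s,averaging_s Durations of the transient and averaging
#'   phases (s).
#' @param dt_ms Integration step for the fourth-order Runge-Kutta binding
#'   update (ms).
#' @return An object of class \code{adwm_synapse_config}.
#' @export
synapse_config <- function(pools, presyn_pool = NULL,
                           presyn = presynaptic_physiology(),
                           tonic_rate_hz = 1, nt_halflife_ms = 100,
                           quantal_increment_nM = 100,
                           equilibration_nM = 500,
                           transient_s = 5, averaging_s = 10,
                           dt_ms = 0.01) {
  if (inherits(pools, "adwm_pool")) pools <- list(pools)
  stopifnot(all(vapply(pools, inherits, logical(1), "adwm_pool")))
  names(pools) <- vapply(pools, `[[`, character(1), "name")
  if (!is.null(presyn_pool) && !presyn_pool %in% names(pools))
    stop("`presyn_pool` must name one of the pools")
  stopifnot(inherits(presyn, "adwm_presyn"))
  if (dt_ms <= 0) stop("`dt_ms` must be positive")
  if (tonic_rate_hz < 0) stop("`tonic_rate_hz` must be non-negative")
  if (transient_s < 0 || averaging_s < 0) stop("phase durations must be non-negative")
  if (nt_halflife_ms <= 0) stop("`nt_halflife_ms` must be positive")
  if (quantal_increment_nM < 0) stop("`quantal_increment_nM` must be non-negative")
  structure(list(pools = pools, presyn_pool = presyn_pool, presyn = presyn,
                 tonic_rate_hz = tonic_rate_hz, nt_halflife_ms = nt_halflife_ms,
                 quantal_increment_nM = quantal_increment_nM,
                 equilibration_nM = equilibration_nM,
                 transient_s = transient_s, averaging_s = averaging_s,
                 dt_ms = dt_ms),
            class = "adwm_synapse_config")
}

#' @export
print.adwm_synapse_config <- function(x, ...) {
  cat(sprintf(paste0("<synapse config> %d pool(s): %s\n",
                     "  tonic %g Hz, NT half-life %g ms, quantal increment %g nM\n",
                     "  phases: equilibrate @ %g nM, %g s transient, %g s averaging, dt %g ms\n"),
              length(x$pools), paste(names(x$pools), collapse = ", "),
              x$tonic_rate_hz, x$nt_halflife_ms, x$quantal_increment_nM,
              x$equilibration_nM, x$transient_s, x$averaging_s, x$dt_ms))
  if (!is.null(x$presyn_pool))
    cat(sprintf("  autoreceptor pool: %s (lag %g ms)\n",
                x$presyn_pool, x$presyn$autoreceptor_lag_ms))
  invisible(x)
}

## Internal: flatten a config into the argument lists the C++ core expects.
## `concentrations` is a named vector of overrides applied to every pool that
## carries a ligand of that name.
.synapse_cpp_args <- function(cfg, concentrations = NULL, halflife_ms = NULL,
                              quantal_scale = 1) {
  pools <- lapply(cfg$pools, function(p) {
    kon <- vapply(p$ligands, `[[`, numeric(1), "kon")
    kd <- vapply(p$ligands, `[[`, numeric(1), "Kd")
    conc <- vapply(p$ligands, `[[`, numeric(1), "concentration")
    if (!is.null(concentrations)) {
      hit <- intersect(names(concentrations), names(conc))
      conc[hit] <- concentrations[hit]
    }
    roles <- vapply(p$ligands, `[[`, character(1), "role")
    nt <- which(roles == "neurotransmitter")
    list(kon = unname(kon), kd = unname(kd), conc = unname(conc),
         nt_idx = if (length(nt)) nt[1] - 1L else -1L,
         names = names(p$ligands))
  })
  presyn_idx <- if (is.null(cfg$presyn_pool)) -1L else
    match(cfg$presyn_pool, names(cfg$pools)) - 1L
  list(pools = pools, presyn_idx = presyn_idx,
       halflife = if (is.null(halflife_ms)) cfg$nt_halflife_ms else halflife_ms,
       q_inc = cfg$quantal_increment_nM * quantal_scale)
}

#' Simulate the receptor-competition synapse
#'
#' Runs the three-phase protocol (analytic equilibration, tonic transient,
#' averaging window) and returns the free-transmitter trace, per-pool
#' occupancy traces and mean activations over the averaging window.  The
#' simulation is fully deterministic: the regular tonic train and the RK4
#' integrator contain no randomness, so identical inputs give bit-identical
#' traces (the \code{seed} argument is accepted for interface uniformity and
#' recorded in the result).
#'
#' @param cfg A \code{\link{synapse_config}}.
#' @param seed Integer recorded in the result (the synapse model itself is
#'   deterministic).
#' @param concentrations Named vector of free-concentration overrides (nM)
#'   for drug/metabolite/tracer ligands, applied in every pool carrying a
#'   ligand of that name.
#' @param halflife_ms Override of the transmitter half-life, e.g. the
#'   AChE-inhibition scaled value from \code{\link{scaled_ach_halflife}}.
#' @param quantal_scale Multiplier on the quantal increment (cholinergic
#'   deficit or compensation scales released transmitter this way).
#' @param spike_times_ms Optional explicit presynaptic spike train (ms),
#'   replacing the regular tonic train (used for forced-firing protocols).
#' @param equilibrate If \code{FALSE}, pools start empty and the free
#'   transmitter starts at \code{nt0_nM} instead of the equilibration phase
#'   (forced-firing / slice-like protocols).
#' @param nt0_nM Initial free transmitter when \code{equilibrate = FALSE}.
#' @param duration_ms Optional total simulated time; defaults to
#'   \code{transient_s + averaging_s}.
#' @param avg_start_ms Start of the averaging window; defaults to the end of
#'   the transient phase.
#' @param record_every_ms Trace storage resolution (integration always runs
#'   at \code{cfg$dt_ms}).
#' @return An object of class \code{adwm_synapse_trace} with elements
#'   \code{time_ms}, \code{free_nM}, \code{occupancy} (list of matrices, one
#'   per pool), \code{mean_activation} (list of named vectors),
#'   \code{mean_free_nM}, \code{peak_free_nM} and \code{seed}.
#' @export
simulate_synapse <- function(cfg, seed = 1L, concentrations = NULL,
                             halflife_ms = NULL, quantal_scale = 1,
                             spike_times_ms = NULL, equilibrate = TRUE,
                             nt0_nM = NULL, duration_ms = NULL,
                             avg_start_ms = NULL, record_every_ms = 1) {
  stopifnot(inherits(cfg, "adwm_synapse_config"))
  args <- .synapse_cpp_args(cfg, concentrations, halflife_ms, quantal_scale)
  if (is.null(duration_ms)) duration_ms <- (cfg$transient_s + cfg$averaging_s) * 1000
  if (is.null(avg_start_ms)) avg_start_ms <- cfg$transient_s * 1000
  if (is.null(spike_times_ms)) {
    spike_times_ms <- if (cfg$tonic_rate_hz > 0)
      seq(0, duration_ms, by = 1000 / cfg$tonic_rate_hz) else numeric(0)
  }
  if (is.unsorted(spike_times_ms)) stop("`spike_times_ms` must be sorted")
  eq_conc <- if (equilibrate) cfg$equilibration_nM else 0
  if (is.null(nt0_nM)) nt0_nM <- eq_conc
  ph <- cfg$presyn
  res <- cpp_simulate_synapse(args$pools, args$presyn_idx,
                              ph$r0, ph$rmax, ph$S, ph$B0,
                              ph$autoreceptor_lag_ms, ph$wf, ph$wd, ph$kf, ph$kd,
                              as.numeric(spike_times_ms), args$halflife,
                              duration_ms, cfg$dt_ms, args$q_inc,
                              nt0_nM, equilibrate, eq_conc,
                              avg_start_ms, record_every_ms)
  pool_names <- names(cfg$pools)
  names(res$occupancy) <- pool_names
  names(res$mean_activation) <- pool_names
  for (i in seq_along(pool_names)) {
    lign <- names(cfg$pools[[i]]$ligands)
    colnames(res$occupancy[[i]]) <- lign
    names(res$mean_activation[[i]]) <- lign
  }
  res$seed <- as.integer(seed)
  class(res) <- "adwm_synapse_trace"
  res
}

#' @export
print.adwm_synapse_trace <- function(x, ...) {
  cat(sprintf("<synapse trace> %d samples, mean free NT %.3g nM, peak %.3g nM\n",
              length(x$time_ms), x$mean_free_nM, x$peak_free_nM))
  for (p in names(x$mean_activation)) {
    a <- x$mean_activation[[p]]
    cat(sprintf("  %-10s %s\n", p,
                paste(sprintf("%s = %.4f", names(a), a), collapse = ", ")))
  }
  invisible(x)
}

#' Export a synapse trace as CSV
#'
#' Columns: \code{time_ms}, \code{free_nM}, then one occupancy column per
#' ligand per pool named \code{<pool>.<ligand>}.
#'
#' @param trace An \code{adwm_synapse_trace}.
#' @param file Path to write.
#' @return The written data frame, invisibly.
#' @export
write_synapse_trace <- function(trace, file) {
  stopifnot(inherits(trace, "adwm_synapse_trace"))
  df <- data.frame(time_ms = trace$time_ms, free_nM = trace$free_nM)
  for (p in names(trace$occupancy)) {
    occ <- trace$occupancy[[p]]
    colnames(occ) <- paste(p, colnames(occ), sep = ".")
    df <- cbind(df, occ)
  }
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
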