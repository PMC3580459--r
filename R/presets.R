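#' Cholinergic synapse preset
#'
#' The calibrated cholinergic synapse: an M2 muscarinic autoreceptor
#' regulating quantal ACh release, and M1, alpha7 and alpha4beta2
#' postsynaptic pools competing for free ACh.  Tonic firing is a regular
#' 7 Hz train (cholinergic nerve endings fire in the 6-8 Hz range) and free
#' ACh decays with the basal half-life of 5 ms set by acetylcholinesterase.
#' The quantal increment derives from 5.5 quanta of 70 molecules per action
#' potential in a 1e-16 L cleft (~6.4 uM per release event).
#'
#' Receptor affinities for free ACh are calibration constants of the
#' platform: the M1 affinity is fixed so that the 8 mg galantamine dose
#' chain (half-life 5 -> 6.33 ms) produces the clinically anchored ~9.1\%
#' increase in mean M1 activation.
#'
#' @param tonic_rate_hz Tonic firing rate, default 7 Hz.
#' @param nt_halflife_ms Basal ACh half-life, default 5 ms.
#' @param quantal_increment_nM Cleft ACh added per baseline release event.
#' @param dt_ms Integration step (ms).
#' @param transient_s,averaging_s Protocol phase durations (s).
#' @return A \code{\link{synapse_config}}.
#' @export
make_cholinergic_synapse <- function(tonic_rate_hz = 7, nt_halflife_ms = 5,
                                     quantal_increment_nM = 6400,
                                     dt_ms = 0.01,
                                     transient_s = 5, averaging_s = 10) {
  kon <- 2e-6  # per nM per ms (2e6 /M/s)
  ach <- function(Kd) ligand("ACh", "neurotransmitter", kon = kon, Kd = Kd)
  pools <- list(
    receptor_pool(ach(.adwm_chol$Kd_M2),  name = "M2"),
    receptor_pool(ach(.adwm_chol$Kd_M1),  name = "M1"),
    receptor_pool(ach(.adwm_chol$Kd_a7),  name = "a7"),
    receptor_pool(ach(.adwm_chol$Kd_a4b2), name = "a4b2"))
  synapse_config(pools, presyn_pool = "M2",
                 presyn = presynaptic_physiology(
                   r0 = 1, rmax = .adwm_chol$rmax, S = .adwm_chol$S,
                   B0 = .adwm_chol$B0, wf = .adwm_chol$wf, wd = .adwm_chol$wd,
                   facilitation_halflife_ms = 90, depression_halflife_ms = 120),
                 tonic_rate_hz = tonic_rate_hz, nt_halflife_ms = nt_halflife_ms,
                 quantal_increment_nM = quantal_increment_nM,
                 equilibration_nM = 500,
                 transient_s = transient_s, averaging_s = averaging_s,
                 dt_ms = dt_ms)
}

# Calibration constants of the cholinergic preset (nM affinities for free
# ACh and presynaptic physiology).  Kd_M1 anchors the galantamine 9.1%
# constraint; Kd_M2 sets the tonic autoreceptor occupancy near B0.
.adwm_chol <- list(Kd_M1 = 304, Kd_M2 = 320, Kd_a7 = 1200, Kd_a4b2 = 320,
                   rmax = 0.5, S = 2, B0 = 0.5, wf = 0.3, wd = 0.2)

#' Serotonergic synapse preset
#'
#' The calibrated serotonergic synapse: a 5-HT1B autoreceptor (functional
#' EC50 8.5 nM for 5-HT; the antagonist-tracer Ki of 23.4 nM and agonist
#' value of 4.2 nM are used for tracer-role ligands) regulating release,
#' with postsynaptic 5-HT2A and 5-HT6 pools.  Tonic firing is 1 Hz (the in
#' vivo serotonergic rate) and the presynaptic physiology carries the
#' fitted forced-firing values: RelSens 7.75, facilitation weight 1.1,
#' depression weight 0.42, half-lives 90 and 120 ms.  The default
#' intra/extrasynaptic free 5-HT ratio is 2, the value selected by the
#' imaging-displacement scan.
#'
#' @param tracer_Kd_nM,drug_Kd_nM Affinities for the tracer- and drug-role
#'   ligands on the 5-HT2A pool (nM); defaults are the setoperone-class
#'   tracer and a generic antagonist, both overridable per experiment.
#' @param intra_extra_ratio Ratio of intrasynaptic over extrasynaptic free
#'   5-HT applied as a release scale (default 2).
#' @param tonic_rate_hz Tonic firing rate, default 1 Hz.
#' @param nt_halflife_ms Free 5-HT half-life (ms).
#' @param dt_ms Integration step (ms).
#' @param transient_s,averaging_s Protocol phase durations (s).
#' @return A \code{\link{synapse_config}} with attribute
#'   \code{"intra_extra_ratio"}.
#' @export
make_serotonergic_synapse <- function(tracer_Kd_nM = 0.3, drug_Kd_nM = 21.8,
                                      intra_extra_ratio = 2,
                                      tonic_rate_hz = 1, nt_halflife_ms = 100,
                                      dt_ms = 0.01,
                                      transient_s = 5, averaging_s = 10) {
  # association rate fast enough that autoreceptor occupancy tracks the
  # transmitter on the few-hundred-ms scale of the release feedback loop
  kon <- 3e-4
  sht <- function(Kd) ligand("5HT", "neurotransmitter", kon = kon, Kd = Kd)
  pools <- list(
    receptor_pool(sht(8.5), name = "5HT1B"),   # functional EC50 for 5-HT
    receptor_pool(list(sht(60),
                       ligand("tracer", "tracer", kon = kon, Kd = tracer_Kd_nM,
                              concentration = 0.5),
                       ligand("drug", "drug", kon = kon, Kd = drug_Kd_nM,
                              concentration = 0)),
                  name = "5HT2A"),
    receptor_pool(sht(21), name = "5HT6"))
  cfg <- synapse_config(pools, presyn_pool = "5HT1B",
                        presyn = serotonergic_presynaptic_fit(),
                        tonic_rate_hz = tonic_rate_hz,
                        nt_halflife_ms = nt_halflife_ms,
                        quantal_increment_nM = 100 * intra_extra_ratio,
                        equilibration_nM = 500,
                        transient_s = transient_s, averaging_s = averaging_s,
                        dt_ms = dt_ms)
  attr(cfg, "intra_extra_ratio") <- intra_extra_ratio
  cfg
}

#' Fitted serotonergic presynaptic physiology
#'
#' The presynaptic parameter set obtained by fitting the five-parameter
#' release physiology to forced-firing voltammetry data: sensitivity
#' (RelSens) 7.75, facilitation weight 1.1, depression weight 0.42, and 90
#' and 120 ms facilitation/depression half-lives.  This is the single
#' source of truth for the serotonergic preset defaults.
#'
#' @return A \code{\link{presynaptic_physiology}}.
#' @export
serotonergic_presynaptic_fit <- function() {
  presynaptic_physiology(r0 = 1, rmax = 0.8, S = 7.75, B0 = 0.55,
                         wf = 1.1, wd = 0.42,
                         facilitation_halflife_ms = 90,
                         depression_halflife_ms = 120)
}

#' Peak free transmitter under forced firing
#'
#' Slice-protocol simulation used for presynaptic calibration: after a
#' tonic warm-up, the terminal is driven either at a fixed frequency for a
#' fixed duration or with a pulse train (a set number of pulses at a set
#' rate, 30 Hz by default), and the peak free transmitter during the
#' stimulation window is reported.
#'
#' @param cfg A \code{\link{synapse_config}}.
#' @param phys Optional \code{\link{presynaptic_physiology}} overriding the
#'   config's (used by the fitting loop).
#' @param freq_hz Forced firing frequency (Hz), or \code{NA} when driving
#'   with a pulse count.
#' @param n_pulses Number of pulses at \code{pulse_rate_hz}, or \code{NA}.
#' @param pulse_rate_hz Rate of the pulse train (default 30 Hz).
#' @param warmup_s Tonic warm-up before stimulation (s).
#' @param stim_s Duration of fixed-frequency stimulation (s).
#' @return Peak free transmitter (nM) during the stimulation window.
#' @export
forced_firing_peak <- function(cfg, phys = NULL, freq_hz = NA, n_pulses = NA,
                               pulse_rate_hz = 30, warmup_s = 2, stim_s = 1) {
  stopifnot(inherits(cfg, "adwm_synapse_config"))
  if (!is.null(phys)) cfg$presyn <- phys
  t0 <- warmup_s * 1000
  warm <- if (cfg$tonic_rate_hz > 0)
    seq(0, t0, by = 1000 / cfg$tonic_rate_hz) else numeric(0)
  warm <- warm[warm < t0 - 1e-6]  # the train must not overlap the stimulus
  if (!is.na(freq_hz)) {
    stim <- t0 + seq(0, stim_s * 1000 - 1e-9, by = 1000 / freq_hz)
    t_end <- t0 + stim_s * 1000 + 200
  } else if (!is.na(n_pulses)) {
    stim <- t0 + (seq_len(n_pulses) - 1) * 1000 / pulse_rate_hz
    t_end <- max(stim) + 200
  } else stop("give either `freq_hz` or `n_pulses`")
  # slice-like protocol: start from rest and let the tonic warm-up build
  # the resting occupancies (no 500 nM equilibration phase)
  tr <- simulate_synapse(cfg, spike_times_ms = c(warm, stim),
                         duration_ms = t_end, avg_start_ms = t0,
                         equilibrate = FALSE, nt0_nM = 0,
                         record_every_ms = 2)
  # peak over the stimulation window only
  sel <- tr$time_ms >= t0
  max(tr$free_nM[sel])
}

#' Synthetic forced-firing ("voltammetry-like") dataset
#'
#' Generates a calibration dataset for the presynaptic fit: simulated peak
#' free transmitter for each stimulus under a known physiology, plus
#' optional Gaussian measurement noise.  This emulates the structure of
#' fast-cyclic-voltammetry slice experiments (frequency series and
#' pulse-count series); it is a synthetic stand-in, not a transcription of
#' any experimental dataset.
#'
#' @param phys The generating \code{\link{presynaptic_physiology}}.
#' @param stimuli Data frame with columns \code{freq_hz} and
#'   \code{n_pulses} (exactly one non-\code{NA} per row) and optionally
#'   \code{pulse_rate_hz} (rate of the pulse train per record, default 30);
#'   see \code{\link{default_voltammetry_stimuli}}.
#' @param noise_sd Gaussian noise standard deviation (nM), non-negative.
#' @param seed Integer seed for the noise.
#' @param cfg Synapse config to simulate under (defaults to the
#'   serotonergic preset at a coarser step for speed).
#' @param ... Passed to \code{\link{forced_firing_peak}}.
#' @return A data frame of class \code{adwm_forced_firing} with the stimulus
#'   columns and \code{peak_nM}; attributes \code{noise_sd} and \code{seed}.
#' @export
generate_voltammetry_fixture <- function(phys, stimuli = default_voltammetry_stimuli(),
                                         noise_sd = 0, seed = 1L,
                                         cfg = NULL, ...) {
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (is.null(cfg)) cfg <- make_serotonergic_synapse(dt_ms = 0.05)
  rate <- if (is.null(stimuli$pulse_rate_hz)) rep(30, nrow(stimuli)) else
    stimuli$pulse_rate_hz
  peaks <- vapply(seq_len(nrow(stimuli)), function(i)
    forced_firing_peak(cfg, phys, freq_hz = stimuli$freq_hz[i],
                       n_pulses = stimuli$n_pulses[i],
                       pulse_rate_hz = rate[i], ...), numeric(1))
  set.seed(seed)
  out <- stimuli
  out$peak_nM <- pmax(0, peaks + stats::rnorm(length(peaks), 0, noise_sd))
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- seed
  class(out) <- c("adwm_forced_firing", class(out))
  out
}

#' Default forced-firing stimulus set
#'
#' A frequency series plus a pulse-count series at 30 Hz, mirroring the
#' structure of the slice calibration protocols.
#'
#' @param freqs Forced firing frequencies (Hz).
#' @param pulses Pulse counts at 30 Hz.
#' @return Data frame with columns \code{freq_hz}, \code{n_pulses}.
#' @export
default_voltammetry_stimuli <- function(freqs = c(1, 2, 5, 10, 20, 30),
                                        pulses = c(5, 10, 20, 40)) {
  data.frame(freq_hz = c(freqs, rep(NA, length(pulses))),
             n_pulses = c(rep(NA, length(freqs)), pulses))
}

#' Fit the presynaptic physiology to forced-firing data
#'
#' Minimises the sum of squared differences between simulated and observed
#' peak free transmitter over the five presynaptic parameters (sensitivity
#' S, facilitation and depression weights, facilitation and depression
#' half-lives).  A coarse full-factorial search over \code{grid} is
#' followed by steepest descent (central-difference gradient in
#' log-parameter space with backtracking line search), stopping when the
#' SSE improvement falls below \code{tol} or after \code{max_iter}
#' iterations.  Deterministic given data and grid.
#'
#' @param data An \code{adwm_forced_firing} dataset (or data frame with
#'   \code{freq_hz}, \code{n_pulses}, \code{peak_nM}).
#' @param cfg Synapse config defining everything but the five fitted
#'   parameters.
#' @param grid Named list of candidate values for \code{S}, \code{wf},
#'   \code{wd}, \code{f_half}, \code{d_half} (full factorial).
#' @param max_iter Steepest-descent iteration cap.
#' @param tol SSE improvement threshold for convergence.
#' @param ... Passed to \code{\link{forced_firing_peak}}.
#' @return List of class \code{adwm_fit_result}: \code{phys} (fitted
#'   physiology), \code{sse}, \code{converged}, \code{degenerate} (single
#'   observation), \code{iterations}, \code{n_evals}.
#' @export
fit_presynaptic_params <- function(data, cfg,
                                   grid = list(S = c(2, 8), wf = c(0.5, 1.5),
                                               wd = c(0.2, 0.6),
                                               f_half = c(60, 120),
                                               d_half = c(80, 160)),
                                   max_iter = 60, tol = 1e-8, ...) {
  stopifnot(nrow(data) >= 1, all(data$peak_nM >= 0))
  needed <- c("S", "wf", "wd", "f_half", "d_half")
  if (!all(needed %in% names(grid))) stop("grid must cover ", paste(needed, collapse = ", "))
  base <- cfg$presyn
  mk <- function(p) presynaptic_physiology(
    r0 = base$r0, rmax = base$rmax, S = p[["S"]], B0 = base$B0,
    wf = p[["wf"]], wd = p[["wd"]],
    facilitation_halflife_ms = p[["f_half"]], depression_halflife_ms = p[["d_half"]],
    autoreceptor_lag_ms = base$autoreceptor_lag_ms)
  n_evals <- 0L
  sse <- function(p) {
    if (any(p <= 0)) return(Inf)
    ph <- tryCatch(mk(p), error = function(e) NULL)
    if (is.null(ph)) return(Inf)
    rate <- if (is.null(data$pulse_rate_hz)) rep(30, nrow(data)) else
      data$pulse_rate_hz
    sim <- tryCatch(vapply(seq_len(nrow(data)), function(i)
      forced_firing_peak(cfg, ph, freq_hz = data$freq_hz[i],
                         n_pulses = data$n_pulses[i],
                         pulse_rate_hz = rate[i], ...), numeric(1)),
      error = function(e) NULL)
    n_evals <<- n_evals + 1L
    if (is.null(sim) || any(!is.finite(sim))) return(Inf)  # reject, keep searching
    sum((sim - data$peak_nM)^2)
  }
  # coarse full-factorial search
  combos <- expand.grid(grid[needed], KEEP.OUT.ATTRS = FALSE)
  vals <- apply(combos, 1, function(r) sse(stats::setNames(as.numeric(r), needed)))
  best <- which.min(vals)
  p <- stats::setNames(as.numeric(combos[best, ]), needed)
  f <- vals[best]
  # gradient descent in log-parameter space, preconditioned by the diagonal
  # curvature (the five parameters act on very different scales), with a
  # backtracking line search
  iterations <- 0L
  converged <- FALSE
  h <- 0.05
  for (it in seq_len(max_iter)) {
    iterations <- it
    fp <- numeric(length(needed)); fm <- numeric(length(needed))
    for (j in seq_along(needed)) {
      pp <- p; pm <- p
      pp[j] <- p[j] * exp(h); pm[j] <- p[j] * exp(-h)
      fp[j] <- sse(pp); fm[j] <- sse(pm)
    }
    g <- (fp - fm) / (2 * h)
    curv <- (fp + fm - 2 * f) / h^2
    if (all(!is.finite(g)) || sqrt(sum(g^2)) == 0) { converged <- TRUE; break }
    step <- ifelse(is.finite(curv) & curv > 0, -g / curv, -sign(g) * 0.1)
    step <- pmax(pmin(step, 0.3), -0.3)   # trust region in log space
    improved <- FALSE
    alpha <- 1
    for (bt in 1:10) {
      cand <- p * exp(alpha * step)
      fc <- sse(cand)
      if (is.finite(fc) && fc < f) {
        improved <- TRUE
        gain <- f - fc
        p <- cand; f <- fc
        if (gain < tol) converged <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!improved) { converged <- TRUE; break }
    if (converged) break
  }
  structure(list(phys = mk(p), params = p, sse = f, converged = converged,
                 degenerate = nrow(data) < length(needed),
                 iterations = iterations, n_evals = n_evals),
            class = "adwm_fit_result")
}

#' @export
print.adwm_fit_result <- function(x, ...) {
  cat(sprintf("<presynaptic fit> SSE = %.4g after %d iteration(s), %d evaluations%s%s\n",
              x$sse, x$iterations, x$n_evals,
              if (x$converged) ", converged" else "",
              if (x$degenerate) " [under-determined: fewer records than parameters]" else ""))
  print(x$phys)
  invisible(x)
}

#' Scan the intra/extrasynaptic free-transmitter ratio
#'
#' Intrasynaptic free transmitter can exceed the extrasynaptically measured
#' level by a factor of 1 to 20.  This scan rescales the intrasynaptic
#' level by each candidate ratio, simulates the tracer displacement for
#' each imaging target, and returns the ratio minimising the squared error
#' against the observed displacements, along with the full error curve.
#'
#' @param ratios Candidate multipliers, within [1, 20].
#' @param targets Data frame of imaging targets with columns
#'   \code{drug_conc_nM}, \code{drug_Kd_nM}, \code{observed_displacement}
#'   (and optionally \code{tracer_Kd_nM}, default 0.3).
#' @param cfg Serotonergic synapse config builder input; defaults to
#'   \code{\link{make_serotonergic_synapse}} at ratio 1 with a coarser
#'   step for speed.
#' @param ... Passed to \code{\link{simulate_displacement}}.
#' @return List of class \code{adwm_ratio_scan}: \code{best_ratio},
#'   \code{error} (named per-ratio SSE), \code{per_target} (matrix of
#'   simulated displacements, ratios x targets).
#' @export
scan_intra_extra_ratio <- function(ratios, targets, cfg = NULL, ...) {
  if (length(ratios) == 0) stop("no ratios to scan")
  if (any(ratios < 1 | ratios > 20)) stop("ratios must lie in [1, 20]")
  if (is.null(targets) || nrow(targets) == 0) stop("empty imaging target list")
  if (is.null(cfg)) cfg <- make_serotonergic_synapse(intra_extra_ratio = 1,
                                                     dt_ms = 0.05,
                                                     transient_s = 2, averaging_s = 5)
  if (is.null(targets$tracer_Kd_nM)) targets$tracer_Kd_nM <- 0.3
  sim <- matrix(NA_real_, length(ratios), nrow(targets),
                dimnames = list(ratios, NULL))
  for (i in seq_along(ratios)) {
    for (j in seq_len(nrow(targets))) {
      cfg_j <- cfg
      lg <- cfg_j$pools[["5HT2A"]]$ligands
      lg[["tracer"]]$Kd <- targets$tracer_Kd_nM[j]
      lg[["drug"]]$Kd <- targets$drug_Kd_nM[j]
      cfg_j$pools[["5HT2A"]]$ligands <- lg
      ex <- tracer_experiment(cfg_j, "5HT2A", "tracer", "drug")
      sim[i, j] <- simulate_displacement(ex, targets$drug_conc_nM[j],
                                         quantal_scale = ratios[i], ...)
    }
  }
  err <- rowSums((sim - matrix(targets$observed_displacement,
                               length(ratios), nrow(targets), byrow = TRUE))^2)
  names(err) <- as.character(ratios)
  structure(list(best_ratio = ratios[which.min(err)], error = err,
                 per_target = sim),
            class = "adwm_ratio_scan")
}

#' @export
print.adwm_ratio_scan <- function(x, ...) {
  cat(sprintf("<ratio scan> best intra/extrasynaptic ratio = %g\n", x$best_ratio))
  print(round(x$error, 5))
  invisible(x)
}
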