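#' Clinical Ki dose from an imaging-reported inhibition level
#'
#' Mass-equation relationship between a clinical dose \code{D} and the
#' enzyme/receptor inhibition level \code{l} measured by radiotracer
#' imaging: \deqn{K_i = D (1 - l) / l.}  For the acetylcholinesterase
#' inhibitors the reported levels are 40\% at 10 mg donepezil, 40\% at
#' 12 mg rivastigmine and 35\% at 16 mg galantamine, giving clinical Ki
#' doses of 15, 18 and 30 mg respectively.
#'
#' @param D Dose in mg, positive.
#' @param l Inhibition level, a fraction strictly between 0 and 1.
#' @return Ki expressed as a dose in mg.
#' @seealso \code{\link{inhibition_from_dose}} (the exact inverse),
#'   \code{\link{ache_inhibitors}} for the shipped preset table.
#' @export
ki_from_inhibition <- function(D, l) {
  if (any(D <= 0)) stop("`D` must be positive")
  if (any(l <= 0 | l >= 1)) stop("`l` must lie strictly in (0, 1)")
  D * (1 - l) / l
}

#' Inhibition level at a dose given the clinical Ki
#'
#' Algebraic inverse of \code{\link{ki_from_inhibition}} under linear
#' pharmacokinetics: \code{l = D / (D + Ki)}.
#'
#' @param D Dose in mg, non-negative.
#' @param Ki Clinical Ki dose in mg, positive.
#' @return Inhibition fraction in [0, 1).
#' @export
inhibition_from_dose <- function(D, Ki) {
  if (any(D < 0)) stop("`D` must be non-negative")
  if (any(Ki <= 0)) stop("`Ki` must be positive")
  D / (D + Ki)
}

#' ACh half-life under acetylcholinesterase inhibition
#'
#' Blocking AChE to a level \code{l} extends the half-life of free ACh in
#' the cleft from its basal value \code{tau0} to \code{tau0 / (1 - l)}.
#' The basal half-life is 5 ms.
#'
#' @param l Inhibition fraction in [0, 1).
#' @param tau0 Basal half-life (ms), default 5.
#' @return Scaled half-life in ms.
#' @export
scaled_ach_halflife <- function(l, tau0 = 5) {
  if (any(l < 0 | l >= 1)) stop("`l` must lie in [0, 1)")
  if (any(tau0 <= 0)) stop("`tau0` must be positive")
  tau0 / (1 - l)
}

#' Molecule count in a synaptic cleft
#'
#' Converts a molar concentration and cleft volume to a molecule count,
#' \code{round(conc * volume * N_A)}.  A concentration of 1 uM corresponds
#' to 30 molecules in a 5e-17 L cleft and 120 molecules in a 2e-16 L cleft,
#' spanning the plausible cholinergic cleft geometry.
#'
#' @param conc_M Concentration in mol/L, non-negative.
#' @param volume_L Cleft volume in litres, positive.
#' @return Integer molecule count.
#' @export
molecules_in_cleft <- function(conc_M, volume_L) {
  if (any(conc_M < 0)) stop("`conc_M` must be non-negative")
  if (any(volume_L <= 0)) stop("`volume_L` must be positive")
  round(conc_M * volume_L * 6.02214076e23)
}

#' Shipped AChE-inhibitor dose-chain presets
#'
#' The three approved acetylcholinesterase inhibitors with their
#' imaging-derived clinical Ki doses (reported to the nearest mg; the
#' printed galantamine value of 30 mg is the canonical preset) and the
#' basal ACh half-life used in the dose chain.
#'
#' @return Data frame with columns \code{drug}, \code{ref_dose_mg},
#'   \code{ref_inhibition}, \code{Ki_mg}, \code{tau0_ms}.
#' @export
ache_inhibitors <- function() {
  data.frame(
    drug = c("donepezil", "galantamine", "rivastigmine"),
    ref_dose_mg = c(10, 16, 12),
    ref_inhibition = c(0.40, 0.35, 0.40),
    Ki_mg = c(15, 30, 18),
    tau0_ms = 5,
    stringsAsFactors = FALSE)
}

#' 5-HT6 receptor activation presets for SB-742457
#'
#' Postsynaptic 5-HT6 receptor activation levels for placebo and the three
#' clinical doses of the 5-HT6 antagonist SB-742457 (which displace 84, 94
#' and 97\% of the radiotracer GSK215083 at 5, 15 and 35 mg).  Shipped as
#' constants because the drug's and tracer's affinities are not public;
#' the activation levels are the platform's calibrated outputs.
#'
#' @return Named numeric vector of activation fractions for doses 0 (placebo),
#'   5, 15 and 35 mg.
#' @export
sb742457_activation <- function() {
  c("0" = 0.406, "5" = 0.129, "15" = 0.051, "35" = 0.031)
}

#' Full AChE-I dose chain
#'
#' Translates a clinical dose of an acetylcholinesterase inhibitor into the
#' scaled ACh half-life: dose -> inhibition level (via the preset clinical
#' Ki) -> half-life \code{tau0 / (1 - l)}.
#'
#' @param drug One of \code{"donepezil"}, \code{"galantamine"},
#'   \code{"rivastigmine"}.
#' @param dose_mg Dose in mg.
#' @return List with \code{drug}, \code{dose_mg}, \code{Ki_mg},
#'   \code{inhibition}, \code{tau0_ms}, \code{halflife_ms}.
#' @export
ache_dose_chain <- function(drug, dose_mg) {
  tab <- ache_inhibitors()
  i <- match(drug, tab$drug)
  if (is.na(i)) stop("unknown AChE inhibitor: ", drug,
                     " (known: ", paste(tab$drug, collapse = ", "), ")")
  l <- inhibition_from_dose(dose_mg, tab$Ki_mg[i])
  list(drug = drug, dose_mg = dose_mg, Ki_mg = tab$Ki_mg[i], inhibition = l,
       tau0_ms = tab$tau0_ms[i],
       halflife_ms = scaled_ach_halflife(l, tab$tau0_ms[i]))
}

#' Tracer displacement experiment
#'
#' Describes a PET-style displacement setup on a synapse model: a tracer and
#' a drug competing with the endogenous transmitter at one pool, and
#' optionally the clinically observed displacement fraction.
#'
#' @param synapse A \code{\link{synapse_config}} whose target pool carries a
#'   tracer-role and a drug-role ligand.
#' @param pool Name of the pool carrying tracer and drug.
#' @param tracer,drug Ligand names within that pool.
#' @param observed_displacement Observed displacement fraction in (0, 1),
#'   or \code{NA} if only forward simulation is needed.
#' @return An object of class \code{adwm_tracer_experiment}.
#' @export
tracer_experiment <- function(synapse, pool, tracer, drug,
                              observed_displacement = NA_real_) {
  stopifnot(inherits(synapse, "adwm_synapse_config"))
  if (!pool %in% names(synapse$pools)) stop("unknown pool: ", pool)
  lign <- names(synapse$pools[[pool]]$ligands)
  if (!tracer %in% lign) stop("tracer ligand not in pool: ", tracer)
  if (!drug %in% lign) stop("drug ligand not in pool: ", drug)
  if (!is.na(observed_displacement) &&
      (observed_displacement <= 0 || observed_displacement >= 1))
    stop("`observed_displacement` must lie in (0, 1)")
  structure(list(synapse = synapse, pool = pool, tracer = tracer, drug = drug,
                 observed_displacement = observed_displacement),
            class = "adwm_tracer_experiment")
}

#' Simulated radiotracer displacement by a drug
#'
#' Runs the synapse twice (drug absent, drug at \code{drug_conc}) and
#' reports \code{1 - occ_with / occ_without} for the tracer's mean
#' occupancy over the averaging window.  Non-decreasing in the drug
#' concentration and saturating at 1.
#'
#' @param exp A \code{\link{tracer_experiment}}.
#' @param drug_conc Free drug concentration (nM), non-negative.
#' @param ... Passed to \code{\link{simulate_synapse}} (e.g.
#'   \code{quantal_scale} for intra/extrasynaptic rescaling).
#' @return Displacement fraction.
#' @export
simulate_displacement <- function(exp, drug_conc, ...) {
  stopifnot(inherits(exp, "adwm_tracer_experiment"))
  if (drug_conc < 0) stop("`drug_conc` must be non-negative")
  base <- simulate_synapse(exp$synapse,
                           concentrations = stats::setNames(0, exp$drug), ...)
  occ0 <- base$mean_activation[[exp$pool]][[exp$tracer]]
  if (occ0 <= 0) stop("undefined displacement: baseline tracer occupancy is zero")
  with <- simulate_synapse(exp$synapse,
                           concentrations = stats::setNames(drug_conc, exp$drug), ...)
  occ1 <- with$mean_activation[[exp$pool]][[exp$tracer]]
  1 - occ1 / occ0
}

#' Functional drug concentration from an observed displacement
#'
#' Inverts \code{\link{simulate_displacement}} by bisection on the drug
#' concentration (displacement is monotone in concentration) until the
#' simulated displacement is within \code{tol} of the observation.  The
#' returned concentration is the free, functional intrasynaptic level that
#' reproduces the imaging result when fed forward.
#'
#' @param exp A \code{\link{tracer_experiment}} with a non-\code{NA}
#'   \code{observed_displacement}.
#' @param lower,upper Concentration bracket in nM.
#' @param tol Displacement tolerance for termination.
#' @param max_iter Iteration cap for the bisection.
#' @param ... Passed to \code{\link{simulate_displacement}}.
#' @return Drug concentration in nM.
#' @export
invert_functional_concentration <- function(exp, lower = 1e-3, upper = 1e6,
                                            tol = 1e-3, max_iter = 200, ...) {
  stopifnot(inherits(exp, "adwm_tracer_experiment"))
  target <- exp$observed_displacement
  if (is.na(target)) stop("experiment has no observed displacement")
  f_lo <- simulate_displacement(exp, lower, ...)
  f_hi <- simulate_displacement(exp, upper, ...)
  if (target < f_lo || target > f_hi)
    stop(sprintf("target displacement %.3g not bracketed in [%g, %g] nM (range %.3g..%.3g)",
                 target, lower, upper, f_lo, f_hi))
  # bisect in log-concentration: displacement spans many decades of Kd
  lo <- log(lower); hi <- log(upper)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- simulate_displacement(exp, exp(mid), ...)
    if (abs(fm - target) < tol) return(exp(mid))
    if (fm < target) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}
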