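## Receptor-activation bookkeeping and the coupling of activation changes
## onto network biophysics (synaptic conductance scaling, the M1/M2
## membrane rule on the delayed rectifier, the 5-HT6 cascade).

.adwm_receptors <- c("D1", "D2", "D4", "M1", "M2", "a7", "a4b2", "a2A",
                     "5HT1A", "5HT2A", "5HT3", "5HT4", "5HT6")

#' Receptor activation set
#'
#' Control (untreated, healthy) and treated activation fractions for the
#' modulatory receptors tracked by the platform.  Receptors not supplied
#' default to a neutral 0.5 control (0.406 for 5-HT6, the calibrated
#' placebo level) with treated equal to control.
#'
#' @param control,treated Named numeric vectors of activation fractions in
#'   [0, 1]; names from \code{D1, D2, D4, M1, M2, a7, a4b2, a2A, 5HT1A,
#'   5HT2A, 5HT3, 5HT4, 5HT6}.
#' @return Object of class \code{adwm_activations} (list with full
#'   \code{control} and \code{treated} vectors).
#' @export
receptor_activations <- function(control = NULL, treated = NULL) {
  base <- stats::setNames(rep(0.5, length(.adwm_receptors)), .adwm_receptors)
  base["5HT6"] <- 0.406
  ctl <- base
  if (!is.null(control)) {
    bad <- setdiff(names(control), .adwm_receptors)
    if (length(bad)) stop("unknown receptors: ", paste(bad, collapse = ", "))
    ctl[names(control)] <- control
  }
  trt <- ctl
  if (!is.null(treated)) {
    bad <- setdiff(names(treated), .adwm_receptors)
    if (length(bad)) stop("unknown receptors: ", paste(bad, collapse = ", "))
    trt[names(treated)] <- treated
  }
  if (any(ctl < 0 | ctl > 1 | trt < 0 | trt > 1))
    stop("activations must lie in [0, 1]")
  structure(list(control = ctl, treated = trt), class = "adwm_activations")
}

#' @export
print.adwm_activations <- function(x, ...) {
  changed <- names(which(abs(x$treated - x$control) > 1e-12))
  cat("<receptor activations>\n")
  if (!length(changed)) cat("  treated = control for all receptors\n")
  for (r in changed)
    cat(sprintf("  %-6s C = %.4f, A = %.4f (%+.1f%%)\n", r,
                x$control[r], x$treated[r],
                100 * (x$treated[r] - x$control[r]) / x$control[r]))
  invisible(x)
}

#' Relative activation change
#'
#' The normalised effect size used by every coupling rule:
#' \code{(A - C) / C} for treated activation \code{A} against the healthy
#' control \code{C}.
#'
#' @param A Treated activation fraction.
#' @param C Control activation fraction, strictly positive.
#' @return Dimensionless relative change.
#' @export
relative_change <- function(A, C) {
  if (any(C <= 0)) stop("control activation must be positive")
  (A - C) / C
}

## epsilon vector for an activation set
.epsilon <- function(act) relative_change(act$treated, act$control)

#' 5-HT6 cascade onto modulator receptors
#'
#' 5-HT6 antagonism raises cortical ACh, DA and NE; the cascade multiplies
#' the treated activations of the dopaminergic (D1, D2, D4), muscarinic
#' (M1, M2) and nicotinic (a7, a4b2) receptors by
#' \code{1 + P_5HT6 * eps}.  The signed term \code{eps} uses the
#' antagonism-raises-modulators convention \code{(C - A)/C} by default:
#' lowering 5-HT6 activation below its control increases the targets, in
#' line with the cascade's pharmacology and a positive coupling constant.
#' Results are clipped to [0, 1].
#'
#' @param act An \code{\link{receptor_activations}} set.
#' @param P_5HT6 Cascade coupling parameter (calibrated optimum 0.025).
#' @param antagonism_raises If \code{FALSE}, uses the literal
#'   \code{(A - C)/C} sign instead.
#' @return The activation set with cascaded treated values.
#' @export
apply_5ht6_cascade <- function(act, P_5HT6, antagonism_raises = TRUE) {
  stopifnot(inherits(act, "adwm_activations"))
  C <- act$control["5HT6"]; A <- act$treated["5HT6"]
  if (C <= 0) stop("5-HT6 control activation must be positive")
  eps <- if (antagonism_raises) (C - A) / C else (A - C) / C
  targets <- c("D1", "D2", "D4", "M1", "M2", "a7", "a4b2")
  act$treated[targets] <- pmin(1, pmax(0, act$treated[targets] *
                                            (1 + P_5HT6 * eps)))
  act
}

#' Muscarinic membrane-potential shift
#'
#' Average resting membrane potential change of pyramidal cells produced by
#' combined M1/M2 modulation:
#' \deqn{\Delta M (mV) = -4 + 6 A_{M1} + 2 (1 - A_{M2}),}
#' bounded on [-4, +4] mV over the unit square.
#'
#' @param A_M1,A_M2 Normalised M1 and M2 activations in [0, 1].
#' @return Shift in mV.
#' @export
membrane_delta <- function(A_M1, A_M2) {
  if (any(A_M1 < 0 | A_M1 > 1 | A_M2 < 0 | A_M2 > 1))
    stop("activations must lie in [0, 1]")
  -4 + 6 * A_M1 + 2 * (1 - A_M2)
}

#' Delayed-rectifier scaling from the membrane rule
#'
#' The muscarinic membrane shift is realised as a change in the delayed
#' rectifying potassium conductance: \code{g' = g (1 + dM * P_M1)}.
#'
#' @param g_Kdr Conductance (any unit).
#' @param dM Membrane shift in mV (see \code{\link{membrane_delta}}).
#' @param P_M1 Coupling parameter (calibrated value 0.075 per mV at the
#'   8 mg galantamine equivalent).
#' @return Scaled conductance.
#' @export
scale_kdr <- function(g_Kdr, dM, P_M1) {
  f <- 1 + dM * P_M1
  if (any(f <= 0)) stop("config error: Kdr coupling too strong (factor <= 0)")
  g_Kdr * f
}

#' Coupling parameters
#'
#' The parameters translating receptor-activation changes into network
#' biophysics.  \code{P_M1} (0.075) and \code{P_5HT6} (0.025) and the
#' relative a7 vs a4b2 weight (2) are the calibrated free-parameter
#' optima; the remaining synaptic couplings are the package's network
#' calibration and are all overridable.
#'
#' @param ... Named overrides.
#' @return List of class \code{adwm_coupling_params}.
#' @export
coupling_params <- function(...) {
  p <- list(P_D1syn = 0.3, P_D1gaba = 0.3, P_D4 = 0.15,
            P_a4b2 = 0.75, rel_a7_a4b2 = 2, P_5HT3 = 0.3,
            P_M1 = 0.075, P_5HT6 = 0.025)
  over <- list(...)
  bad <- setdiff(names(over), c(names(p), "P_a7"))
  if (length(bad)) stop("unknown coupling parameters: ", paste(bad, collapse = ", "))
  p[intersect(names(over), names(p))] <- over[intersect(names(over), names(p))]
  p$P_a7 <- if ("P_a7" %in% names(over)) over$P_a7 else p$rel_a7_a4b2 * p$P_a4b2
  class(p) <- "adwm_coupling_params"
  p
}

#' Apply receptor couplings to a network
#'
#' Sets the neuromodulatory \code{modulation_scale} of every synapse from
#' the relative activation changes, and the pyramidal Kdr scale from the
#' M1/M2 membrane rule.  Scales always start from 1 (the function is
#' idempotent for a fixed activation set); topology and every other
#' parameter are untouched.
#'
#' Rule table (\code{eps_X} the relative change of receptor X):
#' \itemize{
#' \item AMPA and NMDA onto pyramids: \code{(1+P_D1syn eps_D1)(1+P_a7 eps_a7)}
#' \item AMPA onto interneurons: additionally \code{(1+P_D4 eps_D4)}
#' \item NMDA onto interneurons: \code{(1+P_a7 eps_a7)}
#' \item GABA-A onto pyramids: \code{(1+P_D1gaba eps_D1)(1+P_a4b2 eps_a4b2)}
#' \item GABA-A between interneurons: additionally \code{(1+P_5HT3 eps_5HT3)}
#' \item pyramidal Kdr: \code{1 + (dM_treated - dM_control) P_M1}, where dM
#'   is the M1/M2 membrane shift (the control state is the calibration
#'   baseline, so an unchanged activation set leaves Kdr unchanged).
#' }
#'
#' @param net An \code{adwm_network}.
#' @param act An \code{\link{receptor_activations}} set.
#' @param P A \code{\link{coupling_params}} set.
#' @return The modulated network.
#' @export
apply_couplings <- function(net, act, P = coupling_params()) {
  stopifnot(inherits(net, "adwm_network"), inherits(act, "adwm_activations"),
            inherits(P, "adwm_coupling_params"))
  eps <- .epsilon(act)
  syn <- net$synapses
  scale <- rep(1, nrow(syn))
  exc_pyr <- syn$class == "ee"
  scale[exc_pyr] <- (1 + P$P_D1syn * eps["D1"]) * (1 + P$P_a7 * eps["a7"])
  ei_ampa <- syn$class == "ei" & syn$kind == "ampa"
  scale[ei_ampa] <- (1 + P$P_D1syn * eps["D1"]) * (1 + P$P_a7 * eps["a7"]) *
    (1 + P$P_D4 * eps["D4"])
  ei_nmda <- syn$class == "ei" & syn$kind == "nmda"
  scale[ei_nmda] <- 1 + P$P_a7 * eps["a7"]
  gaba_pyr <- syn$class == "ip"
  scale[gaba_pyr] <- (1 + P$P_D1gaba * eps["D1"]) * (1 + P$P_a4b2 * eps["a4b2"])
  gaba_ii <- syn$class == "ii"
  scale[gaba_ii] <- (1 + P$P_D1gaba * eps["D1"]) * (1 + P$P_a4b2 * eps["a4b2"]) *
    (1 + P$P_5HT3 * eps["5HT3"])
  if (any(scale <= 0)) stop("config error: coupling drives a synapse scale <= 0")
  syn$modulation_scale <- scale
  net$synapses <- syn
  dM <- membrane_delta(act$treated["M1"], act$treated["M2"]) -
    membrane_delta(act$control["M1"], act$control["M2"])
  f <- 1 + dM * P$P_M1
  if (f <= 0) stop("config error: Kdr coupling too strong (factor <= 0)")
  net$kdr_scale <- unname(f)
  net
}
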