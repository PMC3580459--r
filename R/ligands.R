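#' Ligand specification for receptor competition
#'
#' A ligand is anything that can occupy the modelled receptor population:
#' the endogenous neurotransmitter, a drug, an active metabolite or a
#' radiotracer.  Binding follows mass-action kinetics with association rate
#' \code{kon} and equilibrium dissociation constant \code{Kd}; the
#' dissociation rate is always the derived quantity \code{koff = kon * Kd}
#' and is never stored independently.
#'
#' @param name Ligand name (character scalar).
#' @param role One of \code{"neurotransmitter"}, \code{"drug"},
#'   \code{"metabolite"}, \code{"tracer"}.
#' @param kon Association rate, per nM per ms.  Must be positive.
#' @param Kd Equilibrium dissociation concentration in nM.  Must be positive.
#' @param concentration Free concentration in nM (constant).  For the
#'   neurotransmitter this is the tonic reference level; during a synapse
#'   simulation the free transmitter is driven by release and decay instead.
#' @return An object of class \code{adwm_ligand}.
#' @examples
#' ach <- ligand("ACh", "neurotransmitter", kon = 2e-6, Kd = 120)
#' @export
ligand <- function(name, role = c("neurotransmitter", "drug", "metabolite", "tracer"),
                   kon, Kd, concentration = 0) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(kon) || length(kon) != 1L || kon <= 0)
    stop("`kon` must be a positive scalar (per nM per ms)")
  if (!is.numeric(Kd) || length(Kd) != 1L || Kd <= 0)
    stop("`Kd` must be a positive scalar (nM)")
  if (!is.numeric(concentration) || length(concentration) != 1L || concentration < 0)
    stop("`concentration` must be a non-negative scalar (nM)")
  structure(list(name = name, role = role, kon = kon, Kd = Kd,
                 concentration = concentration),
            class = "adwm_ligand")
}

#' @export
print.adwm_ligand <- function(x, ...) {
  cat(sprintf("<ligand> %s (%s): kon = %g /nM/ms, Kd = %g nM, koff = %g /ms, C = %g nM\n",
              x$name, x$role, x$kon, x$Kd, x$kon * x$Kd, x$concentration))
  invisible(x)
}

#' Receptor pool
#'
#' One receptor population for which all ligands compete.  Occupancies are
#' expressed as fractions of the total pool (\code{R_total = 1} by default),
#' so the bound amounts are directly the activation fractions.
#'
#' @param ligands List of \code{\link{ligand}} objects binding this pool.
#' @param name Pool name, e.g. the receptor subtype ("M1", "5-HT2A").
#' @param R_total Total receptor concentration; occupancies are reported as
#'   fractions of this.
#' @param bound Optional named numeric vector of initial bound amounts, in
#'   the same units as \code{R_total}.  Defaults to all receptors free.
#' @return An object of class \code{adwm_pool} with elements \code{name},
#'   \code{R_total}, \code{ligands}, \code{bound} and the derived \code{free}.
#' @export
receptor_pool <- function(ligands, name = "receptor", R_total = 1, bound = NULL) {
  if (inherits(ligands, "adwm_ligand")) ligands <- list(ligands)
  stopifnot(length(ligands) >= 1L,
            all(vapply(ligands, inherits, logical(1), "adwm_ligand")))
  nm <- vapply(ligands, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate ligand names in pool")
  names(ligands) <- nm
  if (is.null(bound)) bound <- stats::setNames(numeric(length(nm)), nm)
  bound <- bound[nm]
  if (any(is.na(bound)) || any(bound < 0))
    stop("`bound` must be non-negative and named for every ligand")
  free <- R_total - sum(bound)
  if (free < -1e-12 * R_total) stop("bound amounts exceed R_total")
  structure(list(name = name, R_total = R_total, ligands = ligands,
                 bound = bound, free = free),
            class = "adwm_pool")
}

#' @export
print.adwm_pool <- function(x, ...) {
  cat(sprintf("<receptor pool> %s: R_total = %g, free = %.4g\n",
              x$name, x$R_total, x$free))
  for (nm in names(x$ligands))
    cat(sprintf("  %-12s occ = %.4g\n", nm, x$bound[[nm]] / x$R_total))
  invisible(x)
}

#' Closed-form competitive equilibrium occupancy
#'
#' Steady state of the competitive mass-action system: every ligand held at
#' constant free concentration \code{C_i} occupies the fraction
#' \deqn{R_i/R_o = (C_i/Kd_i) / (1 + \sum_j C_j/Kd_j).}
#' This is the analytic oracle for the ODE integrator
#' (\code{\link{integrate_binding}}) and is exact for constant concentrations.
#'
#' @param ligands List of \code{\link{ligand}} objects (their
#'   \code{concentration} fields are used).
#' @param R_total Total receptor concentration; occupancies returned as
#'   fractions regardless, bound amounts scale with it.
#' @param concentrations Optional named vector overriding the ligand
#'   concentrations (nM).
#' @return Named numeric vector of occupancy fractions, with the free
#'   fraction as attribute \code{"free"}.
#' @export
equilibrium_occupancy <- function(ligands, R_total = 1, concentrations = NULL) {
  if (inherits(ligands, "adwm_ligand")) ligands <- list(ligands)
  nm <- vapply(ligands, `[[`, character(1), "name")
  C <- vapply(ligands, `[[`, numeric(1), "concentration")
  names(C) <- nm
  if (!is.null(concentrations)) C[names(concentrations)] <- concentrations
  Kd <- vapply(ligands, `[[`, numeric(1), "Kd")
  if (any(Kd <= 0)) stop("all Kd must be positive")
  ratio <- C / Kd
  occ <- ratio / (1 + sum(ratio))
  names(occ) <- nm
  attr(occ, "free") <- 1 / (1 + sum(ratio))
  occ
}

#' One Runge-Kutta step of the competitive binding ODE
#'
#' Advances the coupled system \eqn{dR_i/dt = kon_i C_i R_f - kon_i Kd_i R_i}
#' (all ligands share the free pool \eqn{R_f = R_o - \sum R_i}) by a single
#' classical fourth-order Runge-Kutta step.  Continuity is preserved exactly
#' up to floating point because the derivative only exchanges material
#' between bound and free states.
#'
#' @param pool An \code{\link{receptor_pool}}.
#' @param ligands Optional list of ligands overriding those in the pool
#'   (e.g. with updated concentrations).
#' @param dt Step length in ms, positive.
#' @return The pool advanced by one step.
#' @export
integrate_binding <- function(pool, ligands = NULL, dt) {
  stopifnot(inherits(pool, "adwm_pool"))
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be positive")
  lig <- if (is.null(ligands)) pool$ligands else ligands
  kon <- vapply(lig, `[[`, numeric(1), "kon")
  Kd  <- vapply(lig, `[[`, numeric(1), "Kd")
  C   <- vapply(lig, `[[`, numeric(1), "concentration")
  Ro  <- pool$R_total
  deriv <- function(R) kon * C * (Ro - sum(R)) - kon * Kd * R
  R <- pool$bound
  k1 <- deriv(R)
  k2 <- deriv(R + dt / 2 * k1)
  k3 <- deriv(R + dt / 2 * k2)
  k4 <- deriv(R + dt * k3)
  Rn <- R + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (any(Rn < -1e-12) || sum(Rn) > Ro * (1 + 1e-9))
    stop("integration fault: negative bound amount or continuity violation; dt too large")
  Rn <- pmax(Rn, 0)
  pool$bound <- Rn
  pool$free <- Ro - sum(Rn)
  pool
}
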