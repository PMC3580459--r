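#' Presynaptic release physiology
#'
#' Parameters of the autoreceptor-regulated quantal release rule and the
#' spike-history facilitation/depression rule.  Release on each action
#' potential is
#' \deqn{r_{new} = r_0 [1 + r_{max}(1 - 2 A^S/(A^S + B_0^S))]}
#' where \eqn{A} is the presynaptic autoreceptor activation read
#' \code{autoreceptor_lag} ms before the spike, and is further multiplied by
#' the facilitation/depression factor
#' \deqn{1 + \sum_i w_f e^{-k_f \Delta t_i} - w_d e^{-k_d \Delta t_i}}
#' summed over all previous spikes.  Decay rates derive from half-lives as
#' \code{k = ln(2) / t_half}.
#'
#' @param r0 Base release amount (arbitrary release units; converted to a
#'   cleft concentration by the quantal increment of the synapse config).
#' @param rmax Maximum relative change of release, in [0, 1].
#' @param S Autoreceptor sensitivity exponent ("RelSens"), positive.
#' @param B0 Tonic-case presynaptic binding level, in (0, 1].
#' @param wf,wd Facilitation and depression weights, non-negative.
#' @param facilitation_halflife_ms,depression_halflife_ms Decay half-lives in
#'   ms; rates are \code{ln(2)/t_half}.
#' @param autoreceptor_lag_ms Time before release at which the autoreceptor
#'   activation is read (default 150 ms).
#' @return An object of class \code{adwm_presyn}.
#' @export
presynaptic_physiology <- function(r0 = 1, rmax = 0.5, S = 7.75, B0 = 0.5,
                                   wf = 1.1, wd = 0.42,
                                   facilitation_halflife_ms = 90,
                                   depression_halflife_ms = 120,
                                   autoreceptor_lag_ms = 150) {
  if (r0 <= 0) stop("`r0` must be positive")
  if (rmax < 0 || rmax > 1) stop("`rmax` must lie in [0, 1]")
  if (S <= 0) stop("`S` must be positive")
  if (B0 <= 0 || B0 > 1) stop("`B0` must lie in (0, 1]")
  if (wf < 0 || wd < 0) stop("facilitation/depression weights must be >= 0")
  if (facilitation_halflife_ms <= 0 || depression_halflife_ms <= 0)
    stop("half-lives must be positive")
  structure(list(r0 = r0, rmax = rmax, S = S, B0 = B0, wf = wf, wd = wd,
                 kf = log(2) / facilitation_halflife_ms,
                 kd = log(2) / depression_halflife_ms,
                 facilitation_halflife_ms = facilitation_halflife_ms,
                 depression_halflife_ms = depression_halflife_ms,
                 autoreceptor_lag_ms = autoreceptor_lag_ms),
            class = "adwm_presyn")
}

#' @export
print.adwm_presyn <- function(x, ...) {
  cat(sprintf(paste0("<presynaptic physiology> r0 = %g, rmax = %g, S = %g, B0 = %g\n",
                     "  wf = %g, wd = %g, half-lives = %g/%g ms, lag = %g ms\n"),
              x$r0, x$rmax, x$S, x$B0, x$wf, x$wd,
              x$facilitation_halflife_ms, x$depression_halflife_ms,
              x$autoreceptor_lag_ms))
  invisible(x)
}

#' Autoreceptor-regulated release amount
#'
#' Evaluates the release rule at autoreceptor activation \code{A}.  The
#' result lies in \code{[r0 (1 - rmax), r0 (1 + rmax)]} and is strictly
#' decreasing in \code{A}: higher autoreceptor occupancy means stronger
#' negative feedback on release.  At \code{A = B0} the feedback term
#' vanishes and the base amount \code{r0} is released.
#'
#' @param A Activation fraction at the lag time, in [0, 1].
#' @param phys A \code{\link{presynaptic_physiology}} object.
#' @return Release quantity (same units as \code{r0}).
#' @export
release_amount <- function(A, phys) {
  stopifnot(inherits(phys, "adwm_presyn"))
  if (any(A < 0 | A > 1)) stop("`A` must lie in [0, 1]")
  AS <- A^phys$S
  phys$r0 * (1 + phys$rmax * (1 - 2 * AS / (AS + phys$B0^phys$S)))
}

#' Spike-history facilitation/depression factor
#'
#' Multiplier applied to the release amount, computed from all previous
#' spike times: \code{1 + sum(wf exp(-kf dt) - wd exp(-kd dt))}.  An empty
#' history gives exactly 1.
#'
#' @param spike_times Strictly increasing previous spike times (ms), all
#'   earlier than \code{now}.
#' @param now Current spike time (ms).
#' @param phys A \code{\link{presynaptic_physiology}} object.
#' @return Dimensionless multiplier.
#' @export
facilitation_factor <- function(spike_times, now, phys) {
  stopifnot(inherits(phys, "adwm_presyn"))
  if (length(spike_times) == 0L) return(1)
  if (is.unsorted(spike_times, strictly = TRUE) || any(spike_times >= now))
    stop("`spike_times` must be strictly increasing and all earlier than `now`")
  dt <- now - spike_times
  1 + sum(phys$wf * exp(-phys$kf * dt) - phys$wd * exp(-phys$kd * dt))
}
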