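## Hodgkin-Huxley-style channel kinetics for the cortical network.
## Gating follows dx/dt = (x_inf - x)/tau_x with x_inf and tau either given
## directly or derived from alpha/beta rate functions; removable
## singularities of the linoid forms are patched by their limits.

# c*(V - th) / (-1 + exp(-(V - th)/k)), with the L'Hopital limit -c*k at V = th
.linoid <- function(V, c, th, k) {
  x <- V - th
  d <- -1 + exp(-x / k)
  out <- ifelse(abs(d) < 1e-7, -c * k, c * x / d)
  out
}

# c*(V - th) / (-1 + exp((V - th)/k)), limit c*k at V = th
.linoid_p <- function(V, c, th, k) {
  x <- V - th
  d <- -1 + exp(x / k)
  ifelse(abs(d) < 1e-7, c * k, c * x / d)
}

#' Channel gating rates
#'
#' Evaluates the steady-state activation and time constant of every gate of
#' one channel type at membrane potential \code{V}.  Channels follow the
#' conductance form \eqn{g = \bar g x^n y^m}; rates are per ms, potentials
#' in mV.  Alpha/beta formulations return \code{x_inf = a/(a+b)} and
#' \code{tau = 1/(a+b)}; removable singularities are patched by their
#' limits.  The calcium-dependent potassium channel (KCa) is evaluated at
#' the calcium-shifted potential \eqn{V_s = V + 40 \log_{10}(10^4 [Ca]_i)}
#' with \code{[Ca]_i} in molar (floored at 1e-8 to keep the log finite).
#'
#' @param channel One of \code{"Naf"}, \code{"Nap"}, \code{"Kdr"},
#'   \code{"Ks"}, \code{"KCa"}, \code{"Hva"} (pyramidal) or
#'   \code{"int_Naf"}, \code{"int_Kdr"} (interneuron).
#' @param V Membrane potential (mV), may be a vector.
#' @param Cai Intracellular calcium (molar), used by KCa only.
#' @return List with one element per gate (\code{act}, and \code{inact}
#'   where the channel inactivates), each a list of \code{x_inf},
#'   \code{tau_ms} and the gate \code{power}.
#' @export
gating_rates <- function(channel, V, Cai = 5e-8) {
  stopifnot(all(is.finite(V)))
  ab <- function(a, b) list(x_inf = a / (a + b), tau_ms = 1 / (a + b))
  out <- switch(channel,
    Naf = list(
      act = c(ab(.linoid(V, -0.2816, -28, 9.3), .linoid_p(V, 0.2464, -1, 6)),
              power = 3),
      inact = c(ab(0.098 * exp(-(V + 43.1) / 20),
                   1.4 / (1 + exp(-(V + 13.1) / 10))), power = 1)),
    Kdr = list(
      act = c(ab(.linoid(V, -0.018, 13, 25), .linoid_p(V, 0.0054, 23, 12)),
              power = 4)),
    Nap = list(
      act = c(ab(.linoid(V, -0.2816, -17, 9.3), .linoid_p(V, 0.2464, 10, 6)),
              power = 1),
      inact = c(ab(2.0e-5 * exp(-(V + 42.8477) / 4.0248),
                   0.014286 / (1 + exp(-(V - 413.9284) / 148.2589))), power = 1)),
    Hva = list(
      act = list(x_inf = 1 / (1 + exp(-(V + 24.6) / 11.3)),
                 tau_ms = 1.25 / cosh(0.031 * (V + 37.1)), power = 2),
      inact = list(x_inf = 1 / (1 + exp((V + 12.6) / 18.9)),
                   tau_ms = rep(420, length(V)), power = 2)),
    Ks = list(
      act = list(x_inf = 1 / (1 + exp(-(V + 34) / 6.5)),
                 tau_ms = rep(6, length(V)), power = 1),
      inact = list(x_inf = 1 / (1 + exp((V + 65) / 6.6)),
                   tau_ms = 200 + 3200 / (1 + exp(-(V + 63.6) / 4)), power = 1)),
    KCa = {
      Vs <- V + 40 * log10(1e4 * pmax(Cai, 1e-8))
      a <- {
        d <- -1 + exp(-(Vs + 18) / 12)
        ifelse(abs(d) < 1e-7, 0.00642 * 12, (-0.00642 * Vs - 0.1152) / d)
      }
      b <- 1.7 * exp(-(Vs + 152) / 30)
      list(act = list(x_inf = a / (a + b),
                      tau_ms = pmax(1 / (a + b), 1.1), power = 2))
    },
    int_Naf = list(
      act = c(ab(4.2 * exp((V + 34.5) / 11.57), 4.2 * exp(-(V + 34.5) / 27)),
              power = 3),
      inact = c(ab(0.09 * exp(-(V + 45) / 33), 0.09 * exp((V + 45) / 12.2)),
                power = 1)),
    int_Kdr = list(
      act = c(ab(0.3 * exp((V + 35) / 10.67), 0.3 * exp(-(V + 35) / 42.68)),
              power = 4)),
    stop("unknown channel: ", channel))
  out
}

#' Dual-exponential synaptic conductance
#'
#' Conductance time course of one synaptic release:
#' \deqn{g(t) = \bar g\,(e^{-t/\tau_{decay}} - e^{-t/\tau_{rise}})}
#' for \eqn{t \ge 0} (zero at the release instant, peaking at
#' \eqn{t^* = \frac{\tau_r \tau_d}{\tau_d - \tau_r}\ln(\tau_d/\tau_r)}).
#' Multiple releases superpose linearly.
#'
#' @param gbar Maximal conductance (any unit; returned in the same unit).
#' @param tau_rise,tau_decay Rise and decay time constants (ms),
#'   \code{tau_decay > tau_rise > 0}.
#' @param t_since_pre Time since the presynaptic release (ms), vectorised;
#'   non-negative.
#' @param modulation_scale Neuromodulatory multiplier (default 1).
#' @return Conductance value(s).
#' @export
synaptic_conductance <- function(gbar, tau_rise, tau_decay, t_since_pre,
                                 modulation_scale = 1) {
  if (tau_rise <= 0 || tau_decay <= tau_rise)
    stop("need tau_decay > tau_rise > 0")
  if (any(t_since_pre < 0)) stop("`t_since_pre` must be non-negative")
  gbar * modulation_scale *
    (exp(-t_since_pre / tau_decay) - exp(-t_since_pre / tau_rise))
}

#' Voltage-dependent magnesium block of the NMDA receptor
#'
#' Fraction of NMDA current passed at membrane potential \code{V} under
#' physiological magnesium:
#' \deqn{B(V) = 1 / (1 + ([Mg]/3.57)\, e^{-0.062 V})}
#' with \code{[Mg]} in mM.  Equals 1 without magnesium and tends to 0 at
#' strongly hyperpolarised potentials.
#'
#' @param V Membrane potential (mV), vectorised.
#' @param mg_mM Magnesium concentration (mM), non-negative; default 1.
#' @return Block factor in (0, 1].
#' @export
mg_block <- function(V, mg_mM = 1) {
  if (any(mg_mM < 0)) stop("`mg_mM` must be non-negative")
  1 / (1 + (mg_mM / 3.57) * exp(-0.062 * V))
}

#' mGluR5-dependent after-depolarization current
#'
#' Alpha-function current triggered by the memory stimulus that keeps
#' stimulated pyramidal cells excitable for several seconds:
#' \deqn{I(t) = A \,(t/\tau)\, e^{1 - t/\tau},}
#' zero at \code{t = 0}, peaking at exactly \code{A} when \code{t = tau}.
#'
#' @param t_since_stim Time since stimulus onset (ms), non-negative,
#'   vectorised.
#' @param amplitude Peak current \code{A} (same unit as the return value).
#' @param tau Time-to-peak (ms), positive.
#' @return Current value(s).
#' @export
adp_current <- function(t_since_stim, amplitude, tau) {
  if (any(t_since_stim < 0)) stop("`t_since_stim` must be non-negative")
  if (tau <= 0) stop("`tau` must be positive")
  amplitude * (t_since_stim / tau) * exp(1 - t_since_stim / tau)
}
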