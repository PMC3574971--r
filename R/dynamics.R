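#' Wilson-Cowan unit parameters
#'
#' One "neural unit" is a coupled excitatory/inhibitory population pair with a
#' saturating (rectified Naka-Rushton) gain. The defaults place the unit's
#' limit-cycle regime at constant drive currents between roughly 2 and 25, the
#' operating range used by all task scenarios.
#'
#' @param a1 excitatory relaxation rate (per ms).
#' @param a2 inhibitory relaxation rate (per ms).
#' @param b1 excitatory self-drive weight (dimensionless).
#' @param b2 excitatory-to-inhibitory drive weight (dimensionless).
#' @param c1 maximum firing rate (the gain saturates at `c1`).
#' @param c2 semi-saturation constant of the gain (same units as net input).
#'
#' @return An object of class `wm_unit_params`.
#' @export
#' @examples
#' unit_params()
unit_params <- function(a1 = 0.26, a2 = 0.13, b1 = 1.6, b2 = 1.5,
                        c1 = 100, c2 = 30) {
  p <- c(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2)
  if (!all(is.finite(p)) || any(p <= 0))
    stop("all unit parameters must be finite and strictly positive")
  structure(as.list(p), class = "wm_unit_params")
}

#' Rectified Naka-Rushton gain
#'
#' Firing-rate response to net input: `c1 * x^2 / (c2^2 + x^2)` for positive
#' `x`, zero otherwise. Monotone non-decreasing, bounded by `c1`.
#'
#' @param x net input (vectorised).
#' @param c1,c2 maximum rate and semi-saturation constant.
#' @return Firing rate(s) in `[0, c1)`.
#' @export
#' @examples
#' wc_gain(30)   # semi-saturation input: half the maximum rate
wc_gain <- function(x, c1 = 100, c2 = 30) {
  if (c1 <= 0 || c2 <= 0) stop("c1 and c2 must be positive")
  # written as c1 / (1 + (c2/x)^2) so that very large inputs cannot overflow
  ifelse(x > 0, c1 / (1 + (c2 / x)^2), 0)
}

#' Time derivatives of a single Wilson-Cowan unit
#'
#' The excitatory rate `E` relaxes at rate `a1` toward
#' `gain(b1*E - I + K)`; the inhibitory rate `I` relaxes at rate `a2` toward
#' `gain(b2*E)`. External current enters the excitatory equation only.
#'
#' @param E,I excitatory and inhibitory activity rates.
#' @param K external current delivered to the excitatory population.
#' @param params a [unit_params()] object.
#' @return Named numeric vector `c(dE, dI)` (rates of change per ms).
#' @export
#' @examples
#' unit_derivatives(0, 0, 20)   # positive dE at onset of drive
unit_derivatives <- function(E, I, K, params = unit_params()) {
  if (!all(is.finite(c(E, I, K)))) stop("invalid state: non-finite E, I or K")
  c(dE = params$a1 * (-E + wc_gain(params$b1 * E - I + K, params$c1, params$c2)),
    dI = params$a2 * (-I + wc_gain(params$b2 * E, params$c1, params$c2)))
}

#' Net external current of a Memory Unit
#'
#' Combines the unit's base sensory current with a synchronizing contribution
#' from the Central Unit (strength `w1`) and a de-synchronizing contribution
#' from the other Memory Units (strength `w2`):
#' `K0 + w1 * E_central - w2 * sum(E_others)`.
#'
#' @param K0 base (sensory) current.
#' @param E_central excitatory rate of the Central Unit.
#' @param E_others excitatory rates of the other Memory Units.
#' @param w1 Central-to-Memory synchronizing strength (non-negative).
#' @param w2 Memory-to-Memory de-synchronizing strength (non-negative).
#' @return Net current delivered to the unit's excitatory population.
#' @export
memory_drive <- function(K0, E_central, E_others, w1, w2) {
  if (w1 < 0 || w2 < 0) stop("coupling strengths must be non-negative")
  K0 + w1 * E_central - w2 * sum(E_others)
}

# Derivatives of the full network in R, mirroring the compiled core.
# states: list(E = numeric(U), I = numeric(U)), slot 1 = Central Unit.
# Used as the reference for one-step tests and by rk4_step().
network_derivatives <- function(states, t_ms, spec, fired_at = NULL,
                                coincidence = NULL) {
  p <- spec$unit_params
  E <- states$E; I <- states$I
  M <- spec$n_memory
  Kc <- schedule_value(spec$central_schedule, t_ms)
  dE <- numeric(M + 1); dI <- numeric(M + 1)
  pc <- p
  pc$a1 <- p$a1 * spec$central_scale
  pc$a2 <- p$a2 * spec$central_scale
  d <- unit_derivatives(E[1], I[1], Kc, pc)
  dE[1] <- d[1]; dI[1] <- d[2]
  for (j in seq_len(M)) {
    K <- memory_drive(schedule_value(spec$memory_schedules[[j]], t_ms),
                      E[1], E[-c(1, j + 1)], spec$w1, spec$w2)
    if (!is.null(coincidence) && !is.null(fired_at) &&
        j == coincidence$output_unit)
      K <- K + min(coincidence$ramp_rate * (t_ms - fired_at),
                   coincidence$ramp_ceiling)
    d <- unit_derivatives(E[j + 1], I[j + 1], K, p)
    dE[j + 1] <- d[1]; dI[j + 1] <- d[2]
  }
  list(E = dE, I = dI)
}

#' One classical Runge-Kutta (RK4) step of the coupled network
#'
#' Advances all units by one fixed step `dt`, re-evaluating the coupling
#' currents at every sub-stage from the sub-stage states. This is the R
#' reference for the compiled integrator used by [simulate()].
#'
#' @param states list with numeric vectors `E` and `I` of length
#'   `n_memory + 1`; element 1 is the Central Unit.
#' @param t_ms current time in ms.
#' @param dt step size in ms.
#' @param spec a [network_spec()] object.
#' @return Updated `states` list.
#' @export
rk4_step <- function(states, t_ms, dt, spec) {
  if (dt <= 0) stop("dt must be positive")
  f <- function(s, u) network_derivatives(s, u, spec)
  k1 <- f(states, t_ms)
  k2 <- f(list(E = states$E + dt / 2 * k1$E, I = states$I + dt / 2 * k1$I),
          t_ms + dt / 2)
  k3 <- f(list(E = states$E + dt / 2 * k2$E, I = states$I + dt / 2 * k2$I),
          t_ms + dt / 2)
  k4 <- f(list(E = states$E + dt * k3$E, I = states$I + dt * k3$I), t_ms + dt)
  out <- list(E = states$E + dt / 6 * (k1$E + 2 * k2$E + 2 * k3$E + k4$E),
              I = states$I + dt / 6 * (k1$I + 2 * k2$I + 2 * k3$I + k4$I))
  if (!all(is.finite(c(out$E, out$I)))) {
    bad <- which(!is.finite(out$E) | !is.finite(out$I))[1]
    stop(sprintf("integration blow-up in unit %d (1 = central) at t = %.4f ms",
                 bad, t_ms + dt))
  }
  out
}
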