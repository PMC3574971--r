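#' Initial states for a network run
#'
#' By default every unit starts at the quiescent point E = I = 0 plus an
#' independent uniform perturbation in `[0, 0.1]`, giving the units distinct
#' initial phases once driven. Reproducible from `seed`.
#'
#' @param n_units total unit count (Central + Memory).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param perturbation upper bound of the uniform perturbation.
#' @return list with numeric vectors `E` and `I` (element 1 = Central Unit).
#' @export
initial_states <- function(n_units, seed = NULL, perturbation = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  list(E = stats::runif(n_units, 0, perturbation),
       I = stats::runif(n_units, 0, perturbation))
}

#' Simulate the coupled network
#'
#' Integrates the full network with a fixed-step classical Runge-Kutta (RK4)
#' scheme (compiled core); coupling currents are re-evaluated at every RK4
#' sub-stage. Trajectories are stored every `stride` steps (default 1 ms at
#' the default `dt`), which resolves the 6-20 Hz rhythms of interest while
#' keeping results small.
#'
#' @param spec a [network_spec()].
#' @param duration run length in seconds.
#' @param dt integration step in ms (default 0.01).
#' @param init optional initial states as in [initial_states()]; when `NULL`,
#'   perturbed quiescent states are drawn using `seed`.
#' @param seed integer seed used only when `init` is `NULL`.
#' @param stride store every `stride`-th step.
#' @param coincidence optional [coincidence_spec()]; when supplied the
#'   detector is evaluated every step and its ramped current is delivered to
#'   the output unit.
#' @return An object of class `wm_sim`: list with `times` (s), `central_E`,
#'   `central_I`, `memory_E`, `memory_I` (matrices, one column per Memory
#'   Unit), `coincidence` (fired time in s or `NA`, and the stored delivered
#'   current), `dt`, `stride`, `spec`, `init`.
#' @export
#' @examples
#' spec <- network_spec(1, 0, 0, memory_schedules = drive_schedule(0, 20))
#' sim <- simulate(spec, duration = 1, seed = 1)
#' range(sim$memory_E)
simulate <- function(spec, duration, dt = 0.01, init = NULL, seed = NULL,
                     stride = 100, coincidence = NULL) {
  stopifnot(inherits(spec, "wm_network_spec"))
  if (duration <= 0) stop("duration must be positive")
  if (dt <= 0) stop("dt must be positive")
  U <- spec$n_memory + 1L
  if (is.null(init)) init <- initial_states(U, seed = seed)
  if (length(init$E) != U || length(init$I) != U)
    stop("init must supply E and I for central + each memory unit")
  has_co <- !is.null(coincidence)
  co <- if (has_co) coincidence else
    list(input_pair = c(1L, 1L), output_unit = 1L, threshold = Inf,
         ramp_rate = 0, ramp_ceiling = 0)
  p <- spec$unit_params
  res <- simulate_network_cpp(
    spec$n_memory, spec$w1, spec$w2,
    c(p$a1, p$a2, p$b1, p$b2, p$c1, p$c2),
    c(p$a1, p$a2) * spec$central_scale,
    spec$central_schedule$times, spec$central_schedule$values,
    lapply(spec$memory_schedules, `[[`, "times"),
    lapply(spec$memory_schedules, `[[`, "values"),
    duration * 1000, dt, init$E, init$I, as.integer(stride),
    has_co, co$input_pair[1] - 1L, co$input_pair[2] - 1L,
    co$output_unit - 1L, co$threshold, co$ramp_rate, co$ramp_ceiling)
  structure(list(
    times = res$times_ms / 1000,
    central_E = res$E[, 1], central_I = res$I[, 1],
    memory_E = res$E[, -1, drop = FALSE],
    memory_I = res$I[, -1, drop = FALSE],
    coincidence = list(
      fired_time = if (has_co && res$fired_at_ms >= 0)
        res$fired_at_ms / 1000 else NA_real_,
      current = if (has_co) res$coinc_current else NULL),
    dt = dt, stride = as.integer(stride), spec = spec, init = init),
    class = "wm_sim")
}

#' Simulate one uncoupled Wilson-Cowan unit
#'
#' Convenience wrapper used for bifurcation scans and attractor
#' classification: a single Memory Unit with `w1 = w2 = 0`, constant base
#' current `K0`, silent Central Unit.
#'
#' @param K0 constant drive current.
#' @param duration seconds.
#' @param dt step in ms.
#' @param init,seed,stride as in [simulate()].
#' @return A `wm_sim`; the unit's trajectory is `memory_E[, 1]`.
#' @export
simulate_unit <- function(K0, duration = 5, dt = 0.01, init = NULL,
                          seed = NULL, stride = 100) {
  spec <- network_spec(1, 0, 0, memory_schedules = drive_schedule(0, K0))
  simulate(spec, duration, dt = dt, init = init, seed = seed, stride = stride)
}

#' @export
print.wm_sim <- function(x, ...) {
  cat(sprintf(
    "<wm_sim> %d Memory Unit(s) + Central, %.3g s at dt = %g ms (stored every %g ms)\n",
    ncol(x$memory_E), max(x$times), x$dt, x$dt * x$stride))
  if (!is.null(x$coincidence$current))
    cat(sprintf("  coincidence detector: %s\n",
                if (is.na(x$coincidence$fired_time)) "did not fire"
                else sprintf("fired at %.3f s", x$coincidence$fired_time)))
  invisible(x)
}

#' Tidy data frame of a simulation
#'
#' @param x a `wm_sim`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data frame with columns `time_s`, `unit_id`, `role`, `E`, `I`.
#' @export
as.data.frame.wm_sim <- function(x, row.names = NULL, optional = FALSE, ...) {
  M <- ncol(x$memory_E)
  n <- length(x$times)
  central <- data.frame(time_s = x$times, unit_id = "central",
                        role = "central", E = x$central_E, I = x$central_I)
  mem <- do.call(rbind, lapply(seq_len(M), function(j)
    data.frame(time_s = x$times, unit_id = paste0("memory_", j),
               role = "memory", E = x$memory_E[, j], I = x$memory_I[, j])))
  out <- rbind(central, mem)
  rownames(out) <- NULL
  out
}
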