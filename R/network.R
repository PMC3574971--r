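#' Piecewise-constant drive schedule
#'
#' The external current of a unit as a step function of time: `values[i]`
#' applies from `times[i]` (ms) until the next breakpoint. The first
#' breakpoint must be 0 so the current is defined from the start of the run.
#'
#' @param times breakpoint times in ms, sorted, starting at 0.
#' @param values current value from each breakpoint onward.
#' @return An object of class `wm_schedule`.
#' @export
#' @examples
#' drive_schedule(c(0, 1000), c(0, 20))   # quiet, then activated at t = 1 s
drive_schedule <- function(times = 0, values = 0) {
  if (length(times) != length(values) || length(times) < 1)
    stop("times and values must have equal, positive length")
  if (times[1] != 0) stop("the first breakpoint must be at time 0")
  if (is.unsorted(times)) stop("breakpoints must be sorted")
  if (!all(is.finite(times)) || !all(is.finite(values)))
    stop("breakpoints and values must be finite")
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "wm_schedule")
}

#' Evaluate a drive schedule
#' @param schedule a [drive_schedule()].
#' @param t_ms time in ms (vectorised).
#' @return Current value(s) at `t_ms`.
#' @export
schedule_value <- function(schedule, t_ms) {
  idx <- findInterval(t_ms, schedule$times)
  schedule$values[pmax(idx, 1L)]
}

# Append a step change at t_ms (ms); later values are overridden from t_ms on.
schedule_set_from <- function(schedule, t_ms, value) {
  keep <- schedule$times < t_ms
  drive_schedule(c(schedule$times[keep], t_ms),
                 c(schedule$values[keep], value))
}

#' Specification of a working-memory control network
#'
#' One Central Unit plus `n_memory` Memory Units in a star topology. The
#' Central Unit broadcasts a synchronizing current `w1 * E_central` to every
#' Memory Unit; each Memory Unit contributes a de-synchronizing current
#' `-w2 * E` to every other Memory Unit. The Central Unit receives only its
#' own executive (go/no-go) schedule.
#'
#' @param n_memory number of Memory Units (>= 1).
#' @param w1 Central-to-Memory synchronizing strength.
#' @param w2 Memory-to-Memory de-synchronizing strength.
#' @param unit_params shared [unit_params()] for every unit.
#' @param central_schedule [drive_schedule()] of the Central Unit current Kc.
#' @param memory_schedules list of [drive_schedule()], one per Memory Unit
#'   (base current K0). A single schedule is recycled to all units.
#' @param central_scale common factor applied to the Central Unit's
#'   relaxation rates `a1`, `a2`. Rescaling both rates together is a pure
#'   time rescaling of the unit (its bifurcation structure in K is
#'   unchanged), and places the Central Unit in the theta band while the
#'   Memory Units, at the unscaled rates, oscillate faster: the theta-alpha
#'   frequency separation that cross-frequency control relies on. The
#'   default gives the Central Unit ~6 Hz at Kc = 5.
#' @return An object of class `wm_network_spec`.
#' @export
#' @examples
#' network_spec(4, w1 = 0.1, w2 = 0,
#'              central_schedule = drive_schedule(0, 5),
#'              memory_schedules = drive_schedule(0, 20))
network_spec <- function(n_memory, w1, w2, unit_params = wmsync::unit_params(),
                         central_schedule = drive_schedule(),
                         memory_schedules = drive_schedule(),
                         central_scale = 0.324) {
  if (n_memory < 1) stop("n_memory must be >= 1")
  if (w1 < 0 || w2 < 0) stop("coupling strengths must be non-negative")
  if (central_scale <= 0) stop("central_scale must be positive")
  if (inherits(memory_schedules, "wm_schedule"))
    memory_schedules <- rep(list(memory_schedules), n_memory)
  if (length(memory_schedules) != n_memory)
    stop("need one memory schedule per Memory Unit")
  structure(list(n_memory = as.integer(n_memory), w1 = w1, w2 = w2,
                 unit_params = unit_params,
                 central_schedule = central_schedule,
                 memory_schedules = memory_schedules,
                 central_scale = central_scale),
            class = "wm_network_spec")
}

#' Coincidence-detection output stage
#'
#' A threshold element reading the summed excitatory rates of one
#' position-related and one motion-related Memory Unit. On the first crossing
#' of `threshold` the detector latches and delivers a current to the output
#' unit that ramps linearly from 0 at `ramp_rate` per ms up to `ramp_ceiling`,
#' after which it is held. The threshold is only reachable when the two input
#' oscillations peak together, so the stage fires only for a phase-locked
#' pair.
#'
#' @param input_pair integer pair `(position unit, motion unit)` (Memory Unit
#'   indices).
#' @param output_unit Memory Unit index receiving the ramped current.
#' @param threshold summed activity rate that triggers the detector.
#' @param ramp_rate current increase per ms after triggering.
#' @param ramp_ceiling maximum delivered current.
#' @return An object of class `wm_coincidence_spec`.
#' @export
coincidence_spec <- function(input_pair, output_unit, threshold = 160,
                             ramp_rate = 0.1, ramp_ceiling = 20) {
  if (threshold <= 0) stop("threshold must be positive")
  if (length(input_pair) != 2) stop("input_pair must have two unit indices")
  structure(list(input_pair = as.integer(input_pair),
                 output_unit = as.integer(output_unit),
                 threshold = threshold, ramp_rate = ramp_rate,
                 ramp_ceiling = ramp_ceiling),
            class = "wm_coincidence_spec")
}

#' Current delivered by the coincidence detector
#'
#' Pure accounting of the detector's latch-and-ramp rule, usable on recorded
#' traces: zero before the first crossing of `E_pos + E_mot > threshold`;
#' after a crossing at `fired_at`, `min(ramp_rate * (t - fired_at),
#' ramp_ceiling)` regardless of later sub-threshold sums.
#'
#' @param E_pos,E_mot instantaneous excitatory rates of the input pair.
#' @param spec a [coincidence_spec()].
#' @param fired_at time (ms) of the first threshold crossing, or `NULL` if it
#'   has not occurred.
#' @param t_ms current time (ms).
#' @return list with `current` (delivered now) and `fired_at` (possibly newly
#'   set).
#' @export
coincidence_step <- function(E_pos, E_mot, spec, fired_at = NULL, t_ms = 0) {
  if (is.null(fired_at) && E_pos + E_mot > spec$threshold) fired_at <- t_ms
  current <- if (is.null(fired_at)) 0 else
    min(spec$ramp_rate * (t_ms - fired_at), spec$ramp_ceiling)
  list(current = current, fired_at = fired_at)
}
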