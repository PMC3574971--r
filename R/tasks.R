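#' A timed task event
#'
#' Events modify the drive schedules of the network at run time:
#' * `sensory_latch` — a brief visual signal latches the target Memory Unit's
#'   base current to K0 = 20, which persists until an explicit `suppress`.
#' * `go_signal` — the just-activated motion unit activates the Central Unit
#'   (Kc = 5) at the next integration step.
#' * `suppress` — sets the target's base current to 0 ("forget"); the target
#'   may be a Memory Unit index or `"central"`.
#' * `central_off` / `central_on` — set Kc to 0 / 5 (executive reset).
#'
#' @param time event time in seconds (non-negative).
#' @param kind one of `sensory_latch`, `go_signal`, `suppress`,
#'   `central_off`, `central_on`.
#' @param target Memory Unit index, or `"central"`.
#' @return An object of class `wm_task_event`.
#' @export
task_event <- function(time,
                       kind = c("sensory_latch", "go_signal", "suppress",
                                "central_off", "central_on"),
                       target = "central") {
  kind <- match.arg(kind)
  if (time < 0) stop("event times must be non-negative")
  structure(list(time = time, kind = kind, target = target),
            class = "wm_task_event")
}

#' An event-scripted task scenario
#'
#' @param spec a [network_spec()].
#' @param events list of [task_event()]s, sorted by time.
#' @param duration run length in seconds; all events must occur within it.
#' @param coincidence optional [coincidence_spec()].
#' @param roles optional character vector naming each Memory Unit's role
#'   (e.g. `"position"`, `"motion"`, `"output"`).
#' @return An object of class `wm_task_script`.
#' @export
task_script <- function(spec, events, duration, coincidence = NULL,
                        roles = NULL) {
  times <- vapply(events, `[[`, numeric(1), "time")
  if (is.unsorted(times)) stop("events must be sorted by time")
  if (any(times > duration)) stop("event beyond simulation duration")
  ok <- vapply(events, inherits, logical(1), "wm_task_event")
  if (!all(ok)) stop("events must be wm_task_event objects")
  structure(list(spec = spec, events = events, duration = duration,
                 coincidence = coincidence, roles = roles),
            class = "wm_task_script")
}

#' Move-a-dot task script
#'
#' Three Memory Units: a position unit for the shown dot, a motion unit for
#' the arrow, and an output position unit. The dot appears at t = 1 s
#' (latching the position unit), the arrow at t = 2 s (latching the motion
#' unit, whose activation immediately sends the go signal to the Central
#' Unit). The Central Unit phase-locks the position/motion pair
#' (w1 = 0.15 dominates w2 = 0.005); their summed rate then crosses the
#' coincidence threshold of 160 and the detector ramps a current (0 to 20 at
#' 0.1/ms) into the output unit. At t = 3 s the Central Unit and the two
#' input units are suppressed.
#'
#' @return A `wm_task_script` of 4 s duration.
#' @export
build_move_a_dot <- function() {
  spec <- network_spec(3, w1 = 0.15, w2 = 0.005)
  task_script(
    spec,
    events = list(
      task_event(1, "sensory_latch", 1),
      task_event(2, "sensory_latch", 2),
      task_event(2, "go_signal", "central"),
      task_event(3, "suppress", "central"),
      task_event(3, "suppress", 1),
      task_event(3, "suppress", 2)),
    duration = 4,
    coincidence = coincidence_spec(c(1, 2), output_unit = 3),
    roles = c("position", "motion", "output"))
}

#' Multi-task script
#'
#' Four Memory Units: a first dot to be held in memory (latched at
#' t = 0.5 s), then a full move-a-dot sub-task (second dot at 1 s, arrow at
#' 2 s, suppression of the manipulated units at 3 s). With w1 = 0.2 and
#' w2 = 0.02 the synchronizing and de-synchronizing influences compete: the
#' second-dot and motion units lock to each other (and to the Central Unit
#' across frequencies) while the first-dot unit stays active in anti-phase —
#' stored but not processed. After suppression the first-dot unit and the
#' output unit de-synchronize each other into anti-phase.
#'
#' @return A `wm_task_script` of 5 s duration.
#' @export
build_multi_task <- function() {
  spec <- network_spec(4, w1 = 0.2, w2 = 0.02)
  task_script(
    spec,
    events = list(
      task_event(0.5, "sensory_latch", 1),
      task_event(1, "sensory_latch", 2),
      task_event(2, "sensory_latch", 3),
      task_event(2, "go_signal", "central"),
      task_event(3, "suppress", "central"),
      task_event(3, "suppress", 2),
      task_event(3, "suppress", 3)),
    duration = 5,
    coincidence = coincidence_spec(c(2, 3), output_unit = 4),
    roles = c("first_dot", "position", "motion", "output"))
}

#' Error-correction script
#'
#' Three active Memory Units (two position-related at 1 s and 1.5 s, one
#' motion-related at 2 s) under strong competition (w1 = 0.2, w2 = 0.02).
#' The Central Unit first locks one position unit to the motion unit. To
#' model correction of a wrong binding, the Central Unit is shut down at
#' t = 3 s (Kc = 0), leaving only the de-synchronizing influence, and
#' reactivated at t = 4 s (Kc = 5); the lock that re-forms depends on the
#' units' phases at reactivation.
#'
#' @return A `wm_task_script` of 8 s duration.
#' @export
build_error_correction <- function() {
  spec <- network_spec(3, w1 = 0.2, w2 = 0.02)
  task_script(
    spec,
    events = list(
      task_event(1, "sensory_latch", 1),
      task_event(1.5, "sensory_latch", 2),
      task_event(2, "sensory_latch", 3),
      task_event(2, "go_signal", "central"),
      task_event(3, "central_off", "central"),
      task_event(4, "central_on", "central")),
    duration = 8,
    roles = c("position_a", "position_b", "motion"))
}

# Add uniform random onset delays to the sensory latches, using the current
# RNG state. A go_signal is emitted by the motion unit's activation, so it
# inherits the delay of the sensory_latch sharing its scripted time.
jitter_events <- function(script, jitter) {
  events <- script$events
  times0 <- vapply(events, `[[`, numeric(1), "time")
  kinds <- vapply(events, `[[`, character(1), "kind")
  delay <- ifelse(kinds == "sensory_latch",
                  stats::runif(length(events), 0, jitter), 0)
  for (i in which(kinds == "go_signal")) {
    src <- which(kinds == "sensory_latch" & times0 == times0[i])
    if (length(src)) delay[i] <- delay[src[length(src)]]
  }
  for (i in seq_along(events)) events[[i]]$time <- events[[i]]$time + delay[i]
  script$events <- events[order(vapply(events, `[[`, numeric(1), "time"))]
  script
}

# Translate the event list into piecewise-constant drive schedules.
# go_signal takes effect one integration step after its event time.
compile_script <- function(script, dt = 0.01) {
  spec <- script$spec
  central <- spec$central_schedule
  memory <- spec$memory_schedules
  for (ev in script$events) {
    t_ms <- ev$time * 1000
    if (ev$kind == "sensory_latch") {
      j <- as.integer(ev$target)
      if (is.na(j) || j < 1 || j > spec$n_memory)
        stop("sensory_latch target must be a Memory Unit index")
      memory[[j]] <- schedule_set_from(memory[[j]], t_ms, 20)
    } else if (ev$kind == "go_signal") {
      central <- schedule_set_from(central, t_ms + dt, 5)
    } else if (ev$kind == "central_off") {
      central <- schedule_set_from(central, t_ms, 0)
    } else if (ev$kind == "central_on") {
      central <- schedule_set_from(central, t_ms, 5)
    } else if (ev$kind == "suppress") {
      if (identical(ev$target, "central")) {
        central <- schedule_set_from(central, t_ms, 0)
      } else {
        j <- as.integer(ev$target)
        if (is.na(j) || j < 1 || j > spec$n_memory)
          stop("suppress target must be a Memory Unit index or \"central\"")
        memory[[j]] <- schedule_set_from(memory[[j]], t_ms, 0)
      }
    }
  }
  network_spec(spec$n_memory, spec$w1, spec$w2, spec$unit_params,
               central_schedule = central, memory_schedules = memory,
               central_scale = spec$central_scale)
}

#' Run a task scenario and classify its outcome
#'
#' Compiles the script's events into drive schedules, integrates the network
#' (with the coincidence detector evaluated every step if the script has
#' one), and labels every Memory Unit over the final `window` seconds with
#' one of the three memory states:
#' * `quiet` — negligible activity (forgotten),
#' * `active_synchronized` — oscillating and phase-locked to another active
#'   unit (being processed),
#' * `active_desynchronized` — oscillating but locked to no one (stored,
#'   standby).
#'
#' @param script a `wm_task_script`.
#' @param dt integration step (ms).
#' @param seed seed for the random initial perturbations and stimulus-onset
#'   jitter.
#' @param jitter upper bound (s) of the uniform random delay added to each
#'   sensory latch (a go signal moves with the latch that emits it). A quiet
#'   unit relaxes to its stable rest state within tens of ms, so the phase
#'   at which it re-enters the oscillation is set by its activation time;
#'   onset jitter of about one oscillation cycle is what makes runs differ
#'   across seeds, mirroring trial-to-trial variability in stimulus timing.
#' @param stride storage stride (default 0.5 ms at the default `dt`).
#' @param window labelling window at the end of the run (s).
#' @param criterion lock criterion in cycles for pair labelling.
#' @return list with elements `result` (a `wm_sim`) and `outcome`
#'   (a `wm_task_outcome`: per-unit `labels`, `locked_pairs`,
#'   `output_activated`, `activation_time`, `event_log`).
#' @export
#' @examples
#' \donttest{
#' run <- run_task(build_move_a_dot(), seed = 1)
#' run$outcome$labels
#' }
run_task <- function(script, dt = 0.01, seed = NULL, jitter = 0.08,
                     stride = 50, window = 0.5, criterion = 0.01) {
  stopifnot(inherits(script, "wm_task_script"))
  if (!is.null(seed)) set.seed(seed)
  if (jitter > 0) script <- jitter_events(script, jitter)
  compiled <- compile_script(script, dt = dt)
  sim <- simulate(compiled, script$duration, dt = dt,
                  stride = stride, coincidence = script$coincidence)
  outcome <- classify_outcome(sim, script, window = window,
                              criterion = criterion)
  list(result = sim, outcome = outcome)
}

#' Label Memory Units with the three memory states
#'
#' @param sim a `wm_sim`.
#' @param script the `wm_task_script` that produced it.
#' @param window analysis window before the end of the run (s).
#' @param criterion lock criterion (cycles); pairs within `criterion` on
#'   time-averaged folded phase error are `locked_pairs`.
#' @param eps amplitude below which a unit is `quiet`.
#' @return A `wm_task_outcome` list.
#' @export
classify_outcome <- function(sim, script, window = 0.5, criterion = 0.01,
                             eps = 1.0) {
  M <- ncol(sim$memory_E)
  t_end <- max(sim$times)
  sel <- sim$times >= t_end - window
  tt <- sim$times[sel]
  active <- logical(M)
  phases <- vector("list", M)
  for (j in seq_len(M)) {
    tr <- sim$memory_E[sel, j]
    if (max(tr) - min(tr) > eps) {
      active[j] <- TRUE
      phases[[j]] <- tryCatch(extract_phase(tr, tt), error = function(e) NULL)
    }
  }
  locked <- list()
  mean_err <- matrix(NA_real_, M, M)
  for (a in seq_len(M - 1)) for (b in (a + 1):M) {
    if (is.null(phases[[a]]) || is.null(phases[[b]])) next
    err <- relative_phase_error(phases[[a]], phases[[b]])
    mean_err[a, b] <- mean_err[b, a] <- mean(err$error)
    if (mean_err[a, b] < criterion) locked[[length(locked) + 1]] <- c(a, b)
  }
  labels <- rep("quiet", M)
  in_lock <- unique(unlist(locked))
  labels[active] <- "active_desynchronized"
  labels[intersect(which(active), in_lock)] <- "active_synchronized"
  if (!is.null(script$roles)) names(labels) <- script$roles
  structure(list(labels = labels, locked_pairs = locked,
                 pair_mean_error = mean_err,
                 output_activated = !is.na(sim$coincidence$fired_time),
                 activation_time = sim$coincidence$fired_time,
                 event_log = data.frame(
                   time_s = vapply(script$events, `[[`, numeric(1), "time"),
                   kind = vapply(script$events, `[[`, character(1), "kind"),
                   target = vapply(script$events, function(e)
                     as.character(e$target), character(1)))),
            class = "wm_task_outcome")
}

#' @export
print.wm_task_outcome <- function(x, ...) {
  cat("<wm_task_outcome>\n  labels:\n")
  lab <- x$labels
  nm <- if (is.null(names(lab))) paste0("unit_", seq_along(lab)) else names(lab)
  for (i in seq_along(lab)) cat(sprintf("    %-10s %s\n", nm[i], lab[i]))
  if (length(x$locked_pairs))
    cat("  locked pairs:",
        paste(vapply(x$locked_pairs, paste, character(1), collapse = "-"),
              collapse = ", "), "\n")
  cat(sprintf("  output activated: %s\n",
              if (x$output_activated)
                sprintf("yes (%.3f s)", x$activation_time) else "no"))
  invisible(x)
}
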