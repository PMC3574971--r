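#' Load and validate a run configuration
#'
#' YAML (or JSON, a YAML subset) file naming a built-in scenario plus run
#' options. Recognised keys: `scenario` (one of `move-a-dot`, `multi-task`,
#' `error-correction`), `dt` (ms), `duration` (s, overrides the scenario
#' default), `seed`, `stride`, `criterion`, `hold`, `n`, `m`, `eps`, `out`.
#' Unknown keys are rejected; defaults are injected for missing ones.
#'
#' @param path config file path.
#' @return An object of class `wm_config` (a named list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("scenario", "dt", "duration", "seed", "stride", "criterion",
             "hold", "n", "m", "eps", "out")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  defaults <- list(scenario = NULL, dt = 0.01, duration = NULL, seed = 1,
                   stride = 50, criterion = 0.01, hold = 0.3, n = 1, m = 2,
                   eps = 1.0, out = NULL)
  cfg <- utils::modifyList(defaults, raw)
  if (is.null(cfg$scenario) ||
      !cfg$scenario %in% c("move-a-dot", "multi-task", "error-correction"))
    stop("config must name a scenario: move-a-dot, multi-task or error-correction")
  if (cfg$dt <= 0) stop("dt must be positive")
  structure(cfg, class = "wm_config")
}

#' Write a configuration back to YAML
#' @param cfg a `wm_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

#' Build the task script a configuration names
#' @param cfg a `wm_config`.
#' @return A `wm_task_script`.
#' @export
config_script <- function(cfg) {
  script <- switch(cfg$scenario,
                   "move-a-dot" = build_move_a_dot(),
                   "multi-task" = build_multi_task(),
                   "error-correction" = build_error_correction())
  if (!is.null(cfg$duration)) script$duration <- cfg$duration
  script
}

#' Write a simulation as tidy CSV
#'
#' Columns `time_s`, `unit_id`, `role`, `E`, `I`; one row per stored sample
#' per unit.
#'
#' @param result a `wm_sim` (or an already-tidied data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(result, path) {
  df <- if (is.data.frame(result)) result else as.data.frame(result)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy time-series CSV back
#' @param path file written by [write_timeseries()].
#' @return data frame with columns `time_s`, `unit_id`, `role`, `E`, `I`.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "unit_id", "role", "E", "I")
  if (!all(need %in% names(df)))
    stop("not a wmsync time-series file: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' Deterministic fixture for a scenario
#'
#' Bundles a scenario script with the seeded initial perturbations so a run
#' is reproducible bit-for-bit from `(scenario, seed)`.
#'
#' @param seed integer seed.
#' @param scenario scenario name as in [load_config()].
#' @return list with `seed`, `scenario`, `script`, `init`.
#' @export
make_fixture <- function(seed, scenario) {
  script <- switch(scenario,
                   "move-a-dot" = build_move_a_dot(),
                   "multi-task" = build_multi_task(),
                   "error-correction" = build_error_correction(),
                   stop("unknown scenario: ", scenario))
  init <- initial_states(script$spec$n_memory + 1L, seed = seed)
  list(seed = seed, scenario = scenario, script = script, init = init)
}

#' Pairwise synchronization report of a simulation
#'
#' For every pair of oscillating Memory Units: lock time under the stated
#' criterion, time-averaged folded phase error over the final window, each
#' unit's dominant frequency, and the n:m phase-locking value of each unit
#' against the Central Unit.
#'
#' @param sim a `wm_sim`.
#' @param from analyse from this time (s) onward (discard earlier samples).
#' @param criterion,hold lock criterion (cycles) and dwell (s).
#' @param n,m cross-frequency locking ratio against the Central Unit.
#' @param window averaging window for the final error, taken over the last
#'   `window` seconds of each pair's common oscillating support (s).
#' @return data frame with one row per unit pair: `unit_a`, `unit_b`,
#'   `lock_time_s`, `final_error_cycles`, `freq_a_hz`, `freq_b_hz`,
#'   `nm_plv_a`, `nm_plv_b`.
#' @export
sync_report <- function(sim, from = 0, criterion = 0.01, hold = 0.3,
                        n = 1, m = 2, window = 0.5) {
  sel <- sim$times >= from
  tt <- sim$times[sel]
  M <- ncol(sim$memory_E)
  phases <- lapply(seq_len(M), function(j)
    tryCatch(extract_phase(sim$memory_E[sel, j], tt),
             error = function(e) NULL))
  p_central <- tryCatch(extract_phase(sim$central_E[sel], tt),
                        error = function(e) NULL)
  freq <- vapply(seq_len(M), function(j)
    tryCatch(dominant_frequency(sim$memory_E[sel, j], tt),
             error = function(e) NA_real_), numeric(1))
  plv <- vapply(seq_len(M), function(j) {
    if (is.null(phases[[j]]) || is.null(p_central)) return(NA_real_)
    nm_phase_locking(p_central, phases[[j]], n = n, m = m)
  }, numeric(1))
  rows <- list()
  t_end <- max(tt)
  for (a in seq_len(M - 1)) for (b in (a + 1):M) {
    lock <- NA_real_; fin <- NA_real_
    if (!is.null(phases[[a]]) && !is.null(phases[[b]])) {
      err <- relative_phase_error(phases[[a]], phases[[b]])
      lock <- sync_time(err, criterion = criterion, hold = hold)
      late <- err$times >= max(err$times) - window
      if (any(late)) fin <- mean(err$error[late])
    }
    rows[[length(rows) + 1]] <- data.frame(
      unit_a = a, unit_b = b, lock_time_s = lock, final_error_cycles = fin,
      freq_a_hz = freq[a], freq_b_hz = freq[b],
      nm_plv_a = plv[a], nm_plv_b = plv[b])
  }
  do.call(rbind, rows)
}

#' Write a synchronization report as CSV plus a JSON summary
#' @param report data frame from [sync_report()].
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return list of written paths, invisibly.
#' @export
write_sync_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) utils::write.csv(report, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  invisible(list(csv = csv_path, json = json_path))
}
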