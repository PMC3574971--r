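#' Locate oscillation peaks with quadratic interpolation
#'
#' Local maxima above half the post-range of the trace, refined by fitting a
#' parabola through the three samples around each maximum. A minimum peak
#' separation suppresses shoulder maxima of the non-sinusoidal relaxation
#' waveform.
#'
#' @param trace numeric vector (excitatory rate).
#' @param times sample times in seconds (uniform grid).
#' @param min_gap minimum separation between accepted peaks, seconds.
#' @return numeric vector of interpolated peak times (s).
#' @export
find_peaks <- function(trace, times, min_gap = 0.02) {
  stopifnot(length(trace) == length(times))
  n <- length(trace)
  if (n < 3) return(numeric(0))
  thr <- min(trace) + 0.5 * (max(trace) - min(trace))
  cand <- which(diff(sign(diff(trace))) < 0) + 1L
  cand <- cand[trace[cand] >= thr]
  if (!length(cand)) return(numeric(0))
  dt <- times[2] - times[1]
  pk <- vapply(cand, function(i) {
    y1 <- trace[i - 1]; y2 <- trace[i]; y3 <- trace[i + 1]
    den <- y1 - 2 * y2 + y3
    off <- if (den < 0) 0.5 * (y1 - y3) / den else 0
    times[i] + max(-0.5, min(0.5, off)) * dt
  }, numeric(1))
  # enforce min_gap, keeping the earlier peak of any close pair
  keep <- c(TRUE, diff(pk) >= min_gap)
  while (!all(keep)) {
    pk <- pk[keep]
    keep <- c(TRUE, diff(pk) >= min_gap)
  }
  pk
}

#' Instantaneous phase from peak times
#'
#' Defines phase in cycles: it advances by exactly one cycle between
#' consecutive detected peaks and is interpolated linearly in between.
#' Suited to the strongly non-sinusoidal relaxation waveforms of driven
#' Wilson-Cowan units, where analytic-signal phase is distorted by harmonics.
#' The phase is defined only between the first and last peak.
#'
#' @param trace excitatory-rate series.
#' @param times sample times (s).
#' @param min_gap passed to [find_peaks()].
#' @return An object of class `wm_phase`: list with `times`, `phase`
#'   (unwrapped, cycles) and `peak_times`.
#' @export
extract_phase <- function(trace, times, min_gap = 0.02) {
  pk <- find_peaks(trace, times, min_gap = min_gap)
  if (length(pk) < 3)
    stop("too few peaks: trace does not oscillate (need >= 3 peaks)")
  sel <- times >= pk[1] & times <= pk[length(pk)]
  phase <- stats::approx(pk, seq_along(pk) - 1, xout = times[sel])$y
  structure(list(times = times[sel], phase = phase, peak_times = pk),
            class = "wm_phase")
}

#' Relative phase error between two units, in cycles
#'
#' Absolute phase difference folded to `[0, 0.5]` cycles: 0 means in-phase,
#' 0.5 anti-phase. Invariant to adding whole cycles to either series and
#' symmetric in its arguments.
#'
#' @param p1,p2 `wm_phase` objects with overlapping time support.
#' @return list with `times` and `error` (cycles in `[0, 0.5]`).
#' @export
relative_phase_error <- function(p1, p2) {
  lo <- max(p1$times[1], p2$times[1])
  hi <- min(p1$times[length(p1$times)], p2$times[length(p2$times)])
  if (lo >= hi) stop("no overlap between the two phase series")
  tt <- p1$times[p1$times >= lo & p1$times <= hi]
  d <- stats::approx(p1$times, p1$phase, xout = tt)$y -
       stats::approx(p2$times, p2$phase, xout = tt)$y
  frac <- d %% 1
  list(times = tt, error = pmin(frac, 1 - frac))
}

#' First time a pair stays phase-locked
#'
#' Earliest time `t` such that the relative phase error stays below
#' `criterion` throughout `[t, t + hold]`. The hold window (default 0.3 s,
#' about three alpha cycles) prevents transient near-coincidences of two
#' drifting phases from counting as a lock.
#'
#' @param error a list with `times`/`error` as from [relative_phase_error()].
#' @param criterion lock criterion in cycles (default 0.01).
#' @param hold dwell requirement in seconds.
#' @return Lock time in seconds, or `NA` if the pair never locks.
#' @export
sync_time <- function(error, criterion = 0.01, hold = 0.3) {
  if (criterion <= 0) stop("criterion must be positive")
  ok <- error$error < criterion
  n <- length(ok)
  if (!any(ok)) return(NA_real_)
  step <- stats::median(diff(error$times))
  need <- max(1L, ceiling(hold / step))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= need &&
        (starts[k] + need - 1L) <= n)
      return(error$times[starts[k]])
  }
  NA_real_
}

#' Dominant frequency of an oscillating trace
#'
#' Reciprocal of the mean inter-peak interval, which is robust for the
#' quasi-periodic, non-sinusoidal unit waveforms.
#'
#' @param trace excitatory-rate series.
#' @param times sample times (s).
#' @param min_gap passed to [find_peaks()].
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(trace, times, min_gap = 0.02) {
  pk <- find_peaks(trace, times, min_gap = min_gap)
  if (length(pk) < 3)
    stop("too few peaks: trace does not oscillate (need >= 3 peaks)")
  1 / mean(diff(pk))
}

#' Classify a post-transient trajectory as fixed point or limit cycle
#'
#' A trajectory is a limit cycle when its peak-to-trough amplitude exceeds
#' `eps` (default 1.0 rate units, i.e. 1 percent of the maximum rate);
#' otherwise it has settled to a fixed point (quiescent or saturated).
#'
#' @param trace post-transient excitatory-rate series.
#' @param eps amplitude threshold.
#' @return `"fixed_point"` or `"limit_cycle"`.
#' @export
classify_attractor <- function(trace, eps = 1.0) {
  if (max(trace) - min(trace) > eps) "limit_cycle" else "fixed_point"
}

#' Bifurcation scan of a single uncoupled unit over constant current
#'
#' Simulates one uncoupled Wilson-Cowan unit at each current on a grid,
#' discards a transient, classifies each run with [classify_attractor()] and
#' reports the boundary currents as midpoints between adjacent grid points
#' whose classification differs. On `[0, 30]` the unit passes from a
#' quiescent fixed point through a limit-cycle band into a saturated fixed
#' point, so exactly two boundaries are expected.
#'
#' @param K0_min,K0_max,resolution scan grid (resolution must be <= 0.5).
#' @param duration,dt per-point simulation length (s) and step (ms).
#' @param transient discarded initial interval (s).
#' @param eps amplitude threshold for [classify_attractor()].
#' @return An object of class `wm_bifurcation`: list with `K0_grid`,
#'   `amplitude`, `classification`, `boundaries`.
#' @export
#' @examples
#' \donttest{
#' scan <- find_bifurcation_boundaries(0, 30, 0.5)
#' scan$boundaries
#' }
find_bifurcation_boundaries <- function(K0_min = 0, K0_max = 30,
                                        resolution = 0.25, duration = 5,
                                        dt = 0.01, transient = 2, eps = 1.0) {
  if (resolution > 0.5) stop("resolution must be <= 0.5")
  grid <- seq(K0_min, K0_max, by = resolution)
  amp <- vapply(grid, function(K) {
    sim <- simulate_unit(K, duration = duration, dt = dt,
                         init = list(E = c(0, 0.05), I = c(0, 0.02)))
    post <- sim$memory_E[sim$times > transient, 1]
    max(post) - min(post)
  }, numeric(1))
  cls <- ifelse(amp > eps, "limit_cycle", "fixed_point")
  change <- which(cls[-1] != cls[-length(cls)])
  if (!length(change))
    warning("no transition found: classification is uniform over the grid")
  structure(list(K0_grid = grid, amplitude = amp, classification = cls,
                 boundaries = (grid[change] + grid[change + 1]) / 2),
            class = "wm_bifurcation")
}

#' @export
print.wm_bifurcation <- function(x, ...) {
  cat(sprintf("<wm_bifurcation> K0 in [%g, %g], %d points\n",
              min(x$K0_grid), max(x$K0_grid), length(x$K0_grid)))
  cat("  boundaries:", paste(signif(x$boundaries, 4), collapse = ", "), "\n")
  invisible(x)
}

#' n:m cross-frequency phase-locking value
#'
#' Magnitude of the time average of `exp(2i * pi * (n * phi_fast -
#' m * phi_slow))` over the common support: 1 for perfect n:m locking, near 0
#' for independent phases. For theta-alpha coupling between the Central Unit
#' and a locked Memory Unit the natural ratio is near `(n, m) = (1, 2)`.
#'
#' @param p_slow,p_fast `wm_phase` objects (slow and fast oscillator).
#' @param n,m positive integers of the locking ratio.
#' @return Value in `[0, 1]`.
#' @export
nm_phase_locking <- function(p_slow, p_fast, n = 1, m = 2) {
  if (n < 1 || m < 1) stop("n and m must be positive integers")
  lo <- max(p_slow$times[1], p_fast$times[1])
  hi <- min(p_slow$times[length(p_slow$times)],
            p_fast$times[length(p_fast$times)])
  if (lo >= hi) stop("no overlap between the two phase series")
  tt <- p_fast$times[p_fast$times >= lo & p_fast$times <= hi]
  phi_f <- stats::approx(p_fast$times, p_fast$phase, xout = tt)$y
  phi_s <- stats::approx(p_slow$times, p_slow$phase, xout = tt)$y
  Mod(mean(exp(2i * pi * (n * phi_f - m * phi_s))))
}
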