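# Shared helpers: small simulations and pair-error utilities used across
# test files. Everything is generated in code; no stored fixtures.

# Phase objects for the memory units of a simulation over [from, to].
memory_phases <- function(sim, from, to = max(sim$times)) {
  sel <- sim$times >= from & sim$times <= to
  lapply(seq_len(ncol(sim$memory_E)), function(j)
    tryCatch(extract_phase(sim$memory_E[sel, j], sim$times[sel]),
             error = function(e) NULL))
}

# Time-averaged folded phase error of a memory-unit pair over a window.
pair_error <- function(sim, a, b, from, to) {
  ph <- memory_phases(sim, from, to)
  if (is.null(ph[[a]]) || is.null(ph[[b]])) return(NA_real_)
  err <- relative_phase_error(ph[[a]], ph[[b]])
  mean(err$error)
}

# Best-locked memory pair over a window ("a-b"), or "none".
locked_pair_label <- function(sim, from, to, tol = 0.02) {
  M <- ncol(sim$memory_E)
  best <- "none"; bv <- Inf
  for (a in seq_len(M - 1)) for (b in (a + 1):M) {
    m <- pair_error(sim, a, b, from, to)
    if (is.finite(m) && m < bv) { bv <- m; best <- paste0(a, "-", b) }
  }
  if (bv < tol) best else "none"
}

# Synthetic sinusoidal trace sampled at 1 kHz.
sinusoid <- function(freq_hz, duration_s, phase_cycles = 0, fs = 1000) {
  tt <- seq(0, duration_s, by = 1 / fs)
  list(times = tt, trace = sin(2 * pi * (freq_hz * tt + phase_cycles)))
}
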