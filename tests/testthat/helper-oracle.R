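# Independent reference integrator: plain single-step forward Euler at a
# fine time step, written without any package internals. Used as the
# numerical oracle for spike counts of the regular-spiking cell, whose
# resting state is (v, u) = (-70, -14).
euler_reference_counts <- function(currents, window_ms = 1000, dt = 0.05,
                                   a = 0.01, b = 0.2, c = -65, d = 8,
                                   v_peak = 30) {
  n <- length(currents)
  v <- rep(-70, n)
  u <- rep(-14, n)
  counts <- integer(n)
  for (s in seq_len(round(window_ms / dt))) {
    v <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + currents)
    u <- u + dt * a * (b * v - u)
    sp <- v >= v_peak
    if (any(sp)) {
      counts[sp] <- counts[sp] + 1L
      v[sp] <- c
      u[sp] <- u[sp] + d
    }
  }
  counts
}

# spike count of the package integrator under constant drive
package_counts <- function(currents, params = izh_params("RS"),
                           window_ms = 1000, dt = 0.5) {
  vapply(currents, function(I) {
    r <- simulate_window(c(n = I), params, window_ms, dt)
    length(r$times[[1]])
  }, integer(1))
}
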