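#' Izhikevich neuron parameter sets
#'
#' Parameters of the two-variable Izhikevich neuron used throughout the
#' network. The regular-spiking (RS) set models excitatory cells and the
#' fast-spiking (FS) set inhibitory interneurons. A spike is registered when
#' the membrane potential reaches `v_peak` (30 mV), after which `v` is reset
#' to `c` and the recovery variable is incremented by `d`.
#'
#' @param preset `"RS"` (a = 0.01, b = 0.2, c = -65, d = 8) or
#'   `"FS"` (a = 0.1, b = 0.2, c = -65, d = 2).
#' @param a,b,c,d Optional overrides for individual parameters.
#'
#' @return An object of class `izh_params`: a named list with fields
#'   `a`, `b`, `c`, `d`, `v_peak` and `preset`.
#' @examples
#' izh_params("RS")
#' izh_params("FS")$d
#' @export
izh_params <- function(preset = c("RS", "FS"), a = NULL, b = NULL,
                       c = NULL, d = NULL) {
  preset <- match.arg(preset)
  p <- switch(preset,
    RS = list(a = 0.01, b = 0.2, c = -65, d = 8),
    FS = list(a = 0.1,  b = 0.2, c = -65, d = 2))
  if (!is.null(a)) p$a <- a
  if (!is.null(b)) p$b <- b
  if (!is.null(c)) p$c <- c
  if (!is.null(d)) p$d <- d
  p$v_peak <- 30
  p$preset <- preset
  class(p) <- "izh_params"
  p
}

#' Quadratic membrane drift of the Izhikevich model
#'
#' The voltage contribution `0.04 v^2 + 5 v + 140 - u` (without input
#' current). At the resting fixed point of the RS cell, `(-70, -14)`, the
#' drift is exactly zero.
#'
#' @param v Membrane potential (mV). Vectorized.
#' @param u Recovery variable. Vectorized.
#' @return Numeric drift in mV/ms.
#' @examples
#' membrane_derivative(-70, -14)  # 0
#' membrane_derivative(0, 0)      # 140
#' @export
membrane_derivative <- function(v, u) {
  0.04 * v^2 + 5 * v + 140 - u
}

# resting state: the stable root of 0.04 v^2 + 5 v + 140 - b v = 0 with u = b v
rest_state <- function(params) {
  b <- params$b
  disc <- (5 - b)^2 - 4 * 0.04 * 140
  v <- (-(5 - b) - sqrt(disc)) / (2 * 0.04)
  list(v = v, u = b * v)
}

#' Create a neuron state
#'
#' @param v,u Initial membrane potential and recovery variable. Defaults to
#'   the resting fixed point of `params` (with `u = b v`).
#' @param params An [izh_params()] object used to locate rest.
#' @return A list with fields `v`, `u` and `spike_times` (empty).
#' @export
neuron_state <- function(params = izh_params("RS"), v = NULL, u = NULL) {
  r <- rest_state(params)
  if (is.null(v)) v <- r$v
  if (is.null(u)) u <- params$b * v
  list(v = v, u = u, spike_times = numeric(0))
}

#' Advance a single neuron by one Euler step
#'
#' Forward-Euler integration with the voltage update split into two half
#' steps for stability; the recovery variable takes one full step. If the
#' potential reaches 30 mV the spike time is recorded, the trace value is
#' clamped at 30 and the after-spike reset `v <- c`, `u <- u + d` applied.
#'
#' @param state A neuron state as returned by [neuron_state()].
#' @param params An [izh_params()] object.
#' @param input_current Input current for this step.
#' @param dt Step length in ms (> 0).
#' @param t Time (ms) at the end of this step, used to stamp spikes.
#' @return A list with elements `state` (updated; `v` equals the clamped
#'   trace value 30 at a spike sample is *not* kept -- the state holds the
#'   reset value), `spiked` (logical) and `v_trace` (the recorded, clamped
#'   potential for this sample).
#' @examples
#' st <- neuron_state()
#' step_neuron(st, izh_params("RS"), input_current = 0, dt = 0.5, t = 0.5)
#' @export
step_neuron <- function(state, params, input_current, dt, t = dt) {
  stopifnot(dt > 0)
  v <- state$v
  u <- state$u
  v <- v + (dt / 2) * (membrane_derivative(v, u) + input_current)
  v <- v + (dt / 2) * (membrane_derivative(v, u) + input_current)
  u <- u + dt * params$a * (params$b * v - u)
  if (!is.finite(v) || !is.finite(u)) {
    stop("neuron state diverged (non-finite v or u); reduce dt", call. = FALSE)
  }
  spiked <- v >= params$v_peak
  v_trace <- if (spiked) params$v_peak else v
  if (spiked) {
    state$spike_times <- c(state$spike_times, t)
    v <- params$c
    u <- u + params$d
  }
  state$v <- v
  state$u <- u
  list(state = state, spiked = spiked, v_trace = v_trace)
}

#' Simulate a population of neurons over a time window
#'
#' Batch forward-Euler simulation of independent neurons under per-neuron
#' drive, with optional within-group winner-take-all lateral inhibition:
#' once any neuron in the group has spiked, every *other* neuron receives a
#' standing inhibitory current of `w_wta` for the remainder of the window
#' (mutual inhibitory wiring with zero transmission delay, strong enough
#' that one competitor's spike silences the rest of the slot).
#'
#' @param drive Numeric vector of constant input currents (one per neuron)
#'   or a matrix with one row per time step and one column per neuron.
#'   Column/element names become neuron names in the raster.
#' @param params A single [izh_params()] object shared by all neurons, or a
#'   list with one per neuron.
#' @param window_ms Window length in ms (> 0).
#' @param dt Step length in ms.
#' @param states Optional list of initial states (defaults to rest).
#' @param wta Apply winner-take-all lateral inhibition within the group.
#' @param w_wta Standing inhibitory current used when `wta = TRUE`.
#' @param record_v Keep the clamped voltage trace (matrix) in the result.
#'
#' @return An object of class `sm_raster`: a list with `times` (named list
#'   of strictly increasing spike-time vectors, ms), `window_ms`, `dt` and
#'   optionally `v` (trace matrix).
#' @examples
#' r <- simulate_window(c(a = 0, b = 10), izh_params("RS"), window_ms = 200)
#' lengths(r$times)
#' @export
simulate_window <- function(drive, params, window_ms, dt = 0.5,
                            states = NULL, wta = FALSE, w_wta = 0,
                            record_v = FALSE) {
  stopifnot(window_ms > 0, dt > 0)
  if (is.matrix(drive)) {
    n <- ncol(drive)
    nms <- colnames(drive)
  } else {
    n <- length(drive)
    nms <- names(drive)
  }
  if (is.null(nms)) nms <- as.character(seq_len(n))
  if (inherits(params, "izh_params")) params <- rep(list(params), n)
  if (length(params) != n) {
    stop("length of `params` does not match number of neurons", call. = FALSE)
  }
  if (!is.null(states) && length(states) != n) {
    stop("length of `states` does not match number of neurons", call. = FALSE)
  }
  a <- vapply(params, `[[`, numeric(1), "a")
  b <- vapply(params, `[[`, numeric(1), "b")
  cc <- vapply(params, `[[`, numeric(1), "c")
  d <- vapply(params, `[[`, numeric(1), "d")
  vpk <- vapply(params, `[[`, numeric(1), "v_peak")
  if (is.null(states)) {
    rs <- lapply(params, rest_state)
    v <- vapply(rs, `[[`, numeric(1), "v")
    u <- vapply(rs, `[[`, numeric(1), "u")
  } else {
    v <- vapply(states, `[[`, numeric(1), "v")
    u <- vapply(states, `[[`, numeric(1), "u")
  }
  n_steps <- round(window_ms / dt)
  times <- vector("list", n)
  fired <- rep(FALSE, n)
  rs_all <- lapply(params, rest_state)
  v_rest <- vapply(rs_all, `[[`, numeric(1), "v")
  u_rest <- vapply(rs_all, `[[`, numeric(1), "u")
  vmat <- if (record_v) matrix(NA_real_, n_steps, n, dimnames = list(NULL, nms))
  for (s in seq_len(n_steps)) {
    I <- if (is.matrix(drive)) drive[s, ] else drive
    if (wta && any(fired)) {
      # a neuron is inhibited iff some *other* group member has spiked; the
      # inhibition is shunting -- it holds the loser at rest, so an almost
      # initiated spike is aborted and the first spiker keeps the slot
      supp <- (sum(fired) - fired) > 0
      v[supp] <- v_rest[supp]
      u[supp] <- u_rest[supp]
      I <- I - w_wta * supp
    }
    v <- v + (dt / 2) * (membrane_derivative(v, u) + I)
    v <- v + (dt / 2) * (membrane_derivative(v, u) + I)
    u <- u + dt * a * (b * v - u)
    if (any(!is.finite(v)) || any(!is.finite(u))) {
      stop("neuron state diverged (non-finite v or u); reduce dt",
           call. = FALSE)
    }
    sp <- v >= vpk
    if (record_v) vmat[s, ] <- ifelse(sp, vpk, v)
    if (any(sp)) {
      for (i in which(sp)) times[[i]] <- c(times[[i]], s * dt)
      v[sp] <- cc[sp]
      u[sp] <- u[sp] + d[sp]
      fired <- fired | sp
    }
  }
  times <- lapply(times, function(x) if (is.null(x)) numeric(0) else x)
  names(times) <- nms
  out <- list(times = times, window_ms = window_ms, dt = dt)
  if (record_v) out$v <- vmat
  class(out) <- "sm_raster"
  out
}

#' @export
print.sm_raster <- function(x, ...) {
  n_sp <- lengths(x$times)
  cat(sprintf("<sm_raster> %d neurons over %g ms (dt = %g); %d spikes total\n",
              length(x$times), x$window_ms, x$dt, sum(n_sp)))
  active <- n_sp[n_sp > 0]
  if (length(active)) {
    cat("  active:", paste0(names(active), " (", active, ")",
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot a spike raster
#'
#' @param x An `sm_raster`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sm_raster <- function(x, ...) {
  nms <- names(x$times)
  graphics::plot(NA, xlim = c(0, x$window_ms), ylim = c(0.5, length(nms) + 0.5),
                 xlab = "time (ms)", ylab = "", yaxt = "n", ...)
  graphics::axis(2, at = seq_along(nms), labels = nms, las = 1, cex.axis = 0.7)
  for (i in seq_along(nms)) {
    ts <- x$times[[i]]
    if (length(ts)) graphics::segments(ts, i - 0.35, ts, i + 0.35)
  }
  invisible(x)
}

#' Calibrate a constant drive current for a target firing rate
#'
#' Bisects over the input current, using the monotone rate-current relation
#' of the Izhikevich neuron, until a constant current is found whose mean
#' firing rate over `window_ms` (starting from rest) is within 10% of
#' `target_rate`.
#'
#' @param params An [izh_params()] object.
#' @param target_rate Target mean firing rate in Hz (> 0).
#' @param window_ms Simulation window used to measure the rate.
#' @param dt Integration step (ms).
#' @param max_current Upper bound of the bisection interval.
#' @return The calibrated current (scalar).
#' @examples
#' i_theta <- calibrate_band_current(izh_params("RS"), 6)
#' @export
calibrate_band_current <- function(params, target_rate, window_ms = 1000,
                                   dt = 0.5, max_current = 200) {
  stopifnot(target_rate > 0)
  rate_at <- function(I) {
    r <- simulate_window(c(n = I), params, window_ms, dt)
    length(r$times[[1]]) / (window_ms / 1000)
  }
  lo <- 0
  hi <- max_current
  if (rate_at(hi) < target_rate) {
    stop(sprintf("target rate %g Hz unreachable below current %g",
                 target_rate, max_current), call. = FALSE)
  }
  for (iter in 1:48) {
    mid <- (lo + hi) / 2
    if (rate_at(mid) < target_rate) lo <- mid else hi <- mid
  }
  got <- rate_at(hi)
  if (abs(got - target_rate) > 0.1 * target_rate) {
    stop(sprintf(
      "calibration failed: nearest attainable rate %g Hz for target %g Hz",
      got, target_rate), call. = FALSE)
  }
  hi
}

#' Band normalizer for input currents
#'
#' A monotone map from raw summed drive (external stimulation plus synaptic
#' input) to an input current inside a firing band. Drives are clipped below
#' at zero and rescaled so that the reference drive `x_ref` (by default the
#' largest drive in the group) maps to the calibrated band-centre current
#' `i_cal`; drives beyond `x_ref` saturate at `i_cal`, and drives below
#' `rel_threshold * x_ref` are treated as subthreshold and mapped to zero.
#' Output currents therefore always lie in `[0, i_cal]` and `normalize(0)`
#' is 0. The relative drive is raised to the `contrast` exponent before the
#' mapping, which stretches the first-spike latency gap between close
#' competitors so a winner-take-all race resolves on drive rather than on
#' tie-breaking.
#'
#' @param band `"theta"` or `"gamma"`.
#' @param i_cal Calibrated band-centre current (see
#'   [calibrate_band_current()]).
#' @param rel_threshold Relative activation threshold in `[0, 1)`.
#' @param contrast Competition-contrast exponent (>= 1).
#' @return An object of class `sm_band_normalizer`.
#' @export
band_normalizer <- function(band = c("theta", "gamma"), i_cal,
                            rel_threshold = 0.5, contrast = 3) {
  band <- match.arg(band)
  stopifnot(i_cal > 0, rel_threshold >= 0, rel_threshold < 1, contrast >= 1)
  structure(list(band = band, i_cal = i_cal, rel_threshold = rel_threshold,
                 contrast = contrast),
            class = "sm_band_normalizer")
}

#' Apply a band normalizer to a drive vector
#'
#' @param x Numeric vector of raw drives (any sign; negatives clip to zero).
#' @param nrm An [band_normalizer()] object.
#' @param x_ref Reference drive mapping to `i_cal`. Defaults to `max(x, 0)`.
#' @return Currents in `[0, nrm$i_cal]`, same names as `x`.
#' @export
normalize_drive <- function(x, nrm, x_ref = NULL) {
  stopifnot(inherits(nrm, "sm_band_normalizer"))
  y <- pmax(x, 0)
  if (is.null(x_ref)) x_ref <- max(y, 0)
  if (x_ref <= 0) return(y * 0)
  out <- nrm$i_cal * pmin(y / x_ref, 1)^nrm$contrast
  out[y < nrm$rel_threshold * x_ref] <- 0
  out
}
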