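#' Run configuration for a melody network
#'
#' Collects every tunable constant of the model in one validated list:
#' integration step, slot lengths, firing-band targets, STDP constants,
#' tuning width, connection horizon and network size caps. All downstream
#' functions take their defaults from a config object so that a run is fully
#' described by `(config, corpus, seed)`.
#'
#' @param dt Integration step in ms (forward Euler, voltage half-stepped).
#' @param slot_learn_ms Length of one learning note-slot in ms. Each note of
#'   a piece occupies one slot during learning.
#' @param slot_compose_ms Length of one composition note-slot in ms.
#' @param theta_hz Target firing rate (Hz) for the theta band used during
#'   learning; the band spans 4-8 Hz and the default is its midpoint.
#' @param gamma_hz Target firing rate (Hz) for the gamma band used during
#'   composition; the band spans 30-80 Hz.
#' @param a_plus,a_minus STDP potentiation / depression amplitudes.
#' @param tau_plus,tau_minus STDP time constants in ms.
#' @param w_max Upper bound for plastic excitatory weights (lower bound is 0).
#' @param sigma Tuning-curve width in column-index units (shared by the pitch
#'   and duration grids, whose stimuli are both measured in column indices).
#' @param horizon How many note-slots back delayed excitatory synapses are
#'   created during learning (connection horizon).
#' @param layer_cap Maximum number of memory layers (longest learnable track).
#' @param n_interneurons Size of the fast-spiking interneuron pool.
#' @param rel_threshold Relative activation threshold of the band normalizer:
#'   drives below this fraction of the slot's reference drive are silenced.
#' @param contrast Competition-contrast exponent of the band normalizer:
#'   relative drives are raised to this power before mapping to currents,
#'   which widens first-spike latency gaps between close competitors so the
#'   winner-take-all outcome is decided by drive, not by tie-breaking.
#' @param dendritic_delay_ms Small dendritic latency added to postsynaptic
#'   spike times when pairing spikes for STDP, so that coincident pre/post
#'   activity is causal at the synapse.
#' @param know_current_learn External current injected into a knowledge
#'   neuron whose label matches the stimulus during learning.
#' @param know_current_compose Same, during composition (gamma drive).
#' @param seed Integer seed controlling any randomized helper.
#'
#' @return An object of class `sm_config` (a named list).
#' @examples
#' cfg <- sm_config()
#' cfg$theta_hz
#' @export
sm_config <- function(dt = 0.5,
                      slot_learn_ms = 1000,
                      slot_compose_ms = 250,
                      theta_hz = 6,
                      gamma_hz = 50,
                      a_plus = 0.1,
                      a_minus = 0.12,
                      tau_plus = 20,
                      tau_minus = 20,
                      w_max = 10,
                      sigma = 1,
                      horizon = 8,
                      layer_cap = 200,
                      n_interneurons = 10,
                      rel_threshold = 0.5,
                      contrast = 3,
                      dendritic_delay_ms = 2,
                      know_current_learn = 5,
                      know_current_compose = 30,
                      seed = 1L) {
  cfg <- list(
    dt = dt, slot_learn_ms = slot_learn_ms, slot_compose_ms = slot_compose_ms,
    theta_hz = theta_hz, gamma_hz = gamma_hz,
    a_plus = a_plus, a_minus = a_minus,
    tau_plus = tau_plus, tau_minus = tau_minus, w_max = w_max,
    sigma = sigma, horizon = horizon, layer_cap = layer_cap,
    n_interneurons = n_interneurons, rel_threshold = rel_threshold,
    contrast = contrast,
    dendritic_delay_ms = dendritic_delay_ms,
    know_current_learn = know_current_learn,
    know_current_compose = know_current_compose,
    seed = as.integer(seed)
  )
  stopifnot(
    dt > 0, slot_learn_ms > 0, slot_compose_ms > 0,
    theta_hz > 0, gamma_hz > theta_hz,
    a_plus > 0, a_minus > 0, tau_plus > 0, tau_minus > 0, w_max > 0,
    sigma > 0, horizon >= 1, layer_cap >= 1, n_interneurons >= 1,
    rel_threshold >= 0, rel_threshold < 1, contrast >= 1,
    dendritic_delay_ms >= 0,
    know_current_learn > 0, know_current_compose > 0
  )
  class(cfg) <- "sm_config"
  cfg
}

#' @export
print.sm_config <- function(x, ...) {
  cat("<sm_config>  hash:", config_hash(x), "\n")
  flds <- vapply(x, function(v) paste(format(v), collapse = ","), character(1))
  cat(paste0("  ", format(names(flds)), " = ", flds, collapse = "\n"), "\n")
  invisible(x)
}

#' Stable hash of a configuration
#'
#' Rolling polynomial hash over the deparsed configuration, used to stamp
#' logs and model archives so that a model can be matched to the
#' configuration it was trained under.
#'
#' @param cfg An `sm_config` object (or any list of atomic fields).
#' @return An 8-character hexadecimal string.
#' @export
config_hash <- function(cfg) {
  txt <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 17), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  bytes <- utf8ToInt(txt)
  h <- 5381
  # polynomial rolling hash kept below 2^31 so it stays exact in doubles
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# round-trip a config through flat key=value text (used by the CLI)
write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(nm)
    paste0(nm, " = ", paste(format(cfg[[nm]], digits = 17), collapse = ",")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) {
    v <- trimws(paste(p[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- trimws(vapply(kv, `[[`, character(1), 1))
  do.call(sm_config, vals)
}
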