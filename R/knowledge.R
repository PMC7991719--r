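# ---- neuron addressing -----------------------------------------------------
# memory neurons:    "P:<layer>:<col>" / "D:<layer>:<col>"  (0-based columns)
# knowledge neurons: "G:<label>" / "C:<label>" / "T:<label>"
# interneurons:      "I:<k>"

LEVEL_PREFIX <- c(genre = "G", composer = "C", title = "T")

addr_mem <- function(subnet, layer, col) sprintf("%s:%d:%s", subnet, layer, col)

addr_know <- function(level, label) paste0(LEVEL_PREFIX[[level]], ":", label)

mem_col <- function(addr) as.integer(sub("^[PD]:[0-9]+:", "", addr))

#' Activate (and allocate) knowledge-label neurons
#'
#' Knowledge clusters allocate one neuron per distinct label on first
#' encounter; allocation is stable for the lifetime of a model. During
#' learning the genre, composer and title neurons of the current piece are
#' driven simultaneously for one note-slot in the theta band, the hierarchy
#' synapses genre->composer, genre->title and composer->title are ensured,
#' and their weights potentiated by STDP from the slot's co-firing. During
#' composition no allocation happens: an unknown label is an error, since a
#' style that was never learned cannot cue anything.
#'
#' @param model A fitted or in-training [melody_snn()] model.
#' @param labels Named list or vector with entries `genre`, `composer`,
#'   `title` (all three for learning; any subset for lookup).
#' @param phase `"learning"` or `"composition"`.
#' @return A list with `addresses` (named character vector) and, for the
#'   learning phase, `raster` (the knowledge slot raster).
#' @export
activate_labels <- function(model, labels, phase = c("learning", "composition")) {
  phase <- match.arg(phase)
  labels <- as.list(labels)
  if (any(!nzchar(unlist(labels)))) stop("empty knowledge label", call. = FALSE)
  reg <- model$reg
  if (phase == "composition") {
    addrs <- vapply(names(labels), function(level) {
      lbl <- labels[[level]]
      if (!lbl %in% names(reg[[level]])) {
        stop(sprintf("unknown %s label \"%s\": not learned", level, lbl),
             call. = FALSE)
      }
      reg[[level]][[lbl]]
    }, character(1))
    return(list(addresses = addrs))
  }
  stopifnot(all(c("genre", "composer", "title") %in% names(labels)))
  addrs <- vapply(c("genre", "composer", "title"), function(level)
    allocate_label(model, level, labels[[level]]), character(1))
  cfg <- model$config
  # all three matched labels receive the learning current; established
  # hierarchy weights add on top but the normalizer saturates at the
  # calibrated theta drive, keeping the cluster rate-locked to the band
  store <- model$store
  tab <- store$tab
  drive <- vapply(addrs, function(a) {
    inc <- tab[tab$post == a & tab$sign == "exc" & tab$pre %in% addrs, ]
    cfg$know_current_learn + sum(inc$weight)
  }, numeric(1))
  nrm <- band_normalizer("theta", model$cal$i_theta_rs, cfg$rel_threshold,
                         cfg$contrast)
  currents <- normalize_drive(drive, nrm, x_ref = cfg$know_current_learn)
  names(currents) <- addrs
  raster <- simulate_window(currents, model$params$RS, cfg$slot_learn_ms,
                            cfg$dt)
  ensure_synapse(store, addrs[["genre"]], addrs[["composer"]], "exc", 0L)
  ensure_synapse(store, addrs[["genre"]], addrs[["title"]], "exc", 0L)
  ensure_synapse(store, addrs[["composer"]], addrs[["title"]], "exc", 0L)
  apply_stdp(store, raster, raster, stdp_params_from_config(cfg),
             dendritic_delay = cfg$dendritic_delay_ms)
  list(addresses = addrs, raster = raster)
}

# allocate a knowledge neuron and wire its fixed interneuron synapses
allocate_label <- function(model, level, label) {
  reg <- model$reg
  if (label %in% names(reg[[level]])) return(reg[[level]][[label]])
  addr <- addr_know(level, label)
  reg[[level]] <- c(reg[[level]], stats::setNames(addr, label))
  pool <- interneuron_addresses(model)
  if (level %in% c("genre", "composer")) {
    for (p in pool) fixed_synapse(model$store, addr, p, "exc",
                                  model$cal$w_pool_in)
  }
  if (level %in% c("composer", "title")) {
    for (p in pool) fixed_synapse(model$store, p, addr, "inh",
                                  model$cal$w_inh)
  }
  addr
}

interneuron_addresses <- function(model) {
  paste0("I:", seq_len(model$config$n_interneurons))
}

#' Interneuron gating pattern for a composition cue
#'
#' The fast-spiking interneuron pool is driven by the active cue neuron
#' through fixed weights and fires in the gamma band for the whole slot.
#' Its sustained inhibition silences the clusters that must not speak during
#' composition: a genre cue suppresses the composer and title clusters, a
#' composer cue suppresses the title cluster (the genre cluster receives no
#' drive in that circuit and stays silent on its own). With no cue the pool
#' is silent and nothing is suppressed.
#'
#' @param model A [melody_snn()] model.
#' @param cue_level `"genre"` or `"composer"` (or `NA` for no cue).
#' @param cue_address Address of the firing cue neuron (or `NULL`).
#' @return A list with `suppressed` (addresses), `pool_raster` (one
#'   composition slot of pool activity) and `inhibition` (standing
#'   inhibitory drive applied to each suppressed neuron).
#' @export
interneuron_gate <- function(model, cue_level = c("genre", "composer"),
                             cue_address = NULL) {
  cfg <- model$config
  pool <- interneuron_addresses(model)
  if (is.null(cue_address)) {
    empty <- simulate_window(stats::setNames(rep(0, length(pool)), pool),
                             model$params$FS, cfg$slot_compose_ms, cfg$dt)
    return(list(suppressed = character(0), pool_raster = empty,
                inhibition = 0))
  }
  cue_level <- match.arg(cue_level)
  nrm <- band_normalizer("gamma", model$cal$i_gamma_fs, cfg$rel_threshold,
                         cfg$contrast)
  drive <- stats::setNames(rep(model$cal$w_pool_in, length(pool)), pool)
  currents <- normalize_drive(drive, nrm, x_ref = model$cal$w_pool_in)
  pool_raster <- simulate_window(currents, model$params$FS,
                                 cfg$slot_compose_ms, cfg$dt)
  reg <- model$reg
  suppressed <- switch(cue_level,
    genre = c(unname(reg$composer), unname(reg$title)),
    composer = unname(reg$title))
  suppressed <- setdiff(suppressed, cue_address)
  list(suppressed = suppressed, pool_raster = pool_raster,
       inhibition = length(pool) * model$cal$w_inh)
}

# simulate the gated clusters for one composition slot: feedforward drive
# from the active cue through learned hierarchy weights, normalized to the
# gamma band, minus the pool's standing inhibition
gated_cluster_raster <- function(model, gate, active_addrs) {
  cfg <- model$config
  if (!length(gate$suppressed)) return(NULL)
  tab <- model$store$tab
  nrm <- band_normalizer("gamma", model$cal$i_gamma_rs, cfg$rel_threshold,
                         cfg$contrast)
  ff <- vapply(gate$suppressed, function(a) {
    inc <- tab[tab$post == a & tab$sign == "exc" & tab$pre %in% active_addrs, ]
    sum(inc$weight)
  }, numeric(1))
  currents <- normalize_drive(ff, nrm) - gate$inhibition
  names(currents) <- gate$suppressed
  simulate_window(currents, model$params$RS, cfg$slot_compose_ms, cfg$dt)
}
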