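# ---- sequential memory: layered pitch/duration subnetworks -----------------

new_history <- function() {
  h <- new.env(parent = emptyenv())
  h$fired <- list()     # per slot: character vector of active addresses
  h$rasters <- list()   # per slot: named list of spike-time vectors
  h$winners <- list()   # per slot: c(P = addr, D = addr)
  h
}

history_record <- function(h, slot, addrs, times) {
  if (length(h$fired) < slot) {
    h$fired[[slot]] <- character(0)
    h$rasters[[slot]] <- list()
  }
  h$fired[[slot]] <- union(h$fired[[slot]], addrs)
  h$rasters[[slot]] <- utils::modifyList(h$rasters[[slot]], times)
  invisible(h)
}

# raw drive of every column of one memory layer: external tuning (optional)
# plus slot-delayed synaptic input from previously active neurons
layer_drive <- function(model, subnet, layer, stim_col = NULL, fired = list()) {
  grid <- if (subnet == "P") model$grids$pitch else model$grids$duration
  n_col <- length(grid$preferences)
  drv <- stats::setNames(rep(0, n_col), as.character(seq_len(n_col) - 1L))
  if (!is.null(stim_col)) drv <- drv + grid_drive(grid, stim_col)
  tab <- model$store$tab
  prefix <- sprintf("%s:%d:", subnet, layer)
  posts <- unique(tab$post[startsWith(tab$post, prefix)])
  for (p in posts) {
    col <- as.character(mem_col(p))
    drv[col] <- drv[col] + delivered_input(model$store, p, fired, layer)
  }
  drv
}

#' Present one note to the memory network (learning slot)
#'
#' Simulates a single learning note-slot. Tuning currents for the note's
#' pitch and duration drive the columns of layer `slot` in both
#' subnetworks; the preferring column wins the within-layer competition and
#' fires in the theta band while lateral inhibition silences the rest of
#' the layer. Plastic excitatory synapses are then ensured and updated by
#' STDP: (a) from the winner of every earlier layer `k` within the
#' connection horizon, with transmission delay `slot - k` note-slots, (b)
#' from every active knowledge neuron to the winner, and (c) from the
#' winner back to the title neuron (memory-title feedback). All potentials
#' decay back to rest between slots.
#'
#' @param model A [melody_snn()] model being trained.
#' @param x An [note()].
#' @param slot Note-slot index (1-based layer index).
#' @param knowledge Result of [activate_labels()] for the current piece
#'   (learning phase), supplying the active knowledge addresses and their
#'   slot raster.
#' @return The slot raster (class `sm_raster`) holding the two winners and
#'   the knowledge neurons, invisibly. The model is updated in place.
#' @export
present_note <- function(model, x, slot, knowledge) {
  cfg <- model$config
  if (slot > cfg$layer_cap) {
    stop(sprintf("slot %d exceeds the layer cap (%d)", slot, cfg$layer_cap),
         call. = FALSE)
  }
  if (is.null(model$state$history)) model$state$history <- new_history()
  h <- model$state$history
  know_addrs <- unname(knowledge$addresses)
  know_times <- knowledge$raster$times
  cols <- note_to_columns(x)
  nrm <- band_normalizer("theta", model$cal$i_theta_rs, cfg$rel_threshold,
                         cfg$contrast)
  sp <- stdp_params_from_config(cfg)
  slot_times <- know_times
  for (subnet in c("P", "D")) {
    stim_col <- if (subnet == "P") cols[["pitch"]] else cols[["duration"]]
    fired <- h$fired
    fired[[slot]] <- c(if (slot <= length(h$fired)) h$fired[[slot]] else
      character(0), know_addrs)
    drv <- layer_drive(model, subnet, slot, stim_col, fired)
    currents <- normalize_drive(drv, nrm)
    driven <- currents[currents > 0]
    if (!length(driven)) next
    raster <- simulate_window(driven, model$params$RS, cfg$slot_learn_ms,
                              cfg$dt, wta = TRUE, w_wta = model$cal$w_inh)
    win_col <- select_winner(raster)
    win_addr <- addr_mem(subnet, slot, win_col)
    win_times <- raster$times[[as.character(win_col)]]
    # (a) delayed synapses from earlier winners within the horizon
    for (k in if (slot > 1) seq(max(1, slot - cfg$horizon), slot - 1) else integer(0)) {
      if (k > length(h$winners) || is.null(h$winners[[k]])) next
      pre_addr <- unname(h$winners[[k]][subnet])
      if (length(pre_addr) != 1 || is.na(pre_addr)) next
      ensure_synapse(model$store, pre_addr, win_addr, "exc",
                     delay_slots = slot - k)
      apply_stdp(model$store,
                 stats::setNames(list(h$rasters[[k]][[pre_addr]]), pre_addr),
                 stats::setNames(list(win_times), win_addr),
                 sp, dendritic_delay = cfg$dendritic_delay_ms)
    }
    # (b) knowledge -> winner
    for (ka in know_addrs) {
      ensure_synapse(model$store, ka, win_addr, "exc", delay_slots = 0L)
    }
    apply_stdp(model$store, know_times,
               stats::setNames(list(win_times), win_addr),
               sp, dendritic_delay = cfg$dendritic_delay_ms)
    # (c) memory -> title feedback
    title_addr <- knowledge$addresses[["title"]]
    ensure_synapse(model$store, win_addr, title_addr, "exc", delay_slots = 0L)
    apply_stdp(model$store, stats::setNames(list(win_times), win_addr),
               know_times[title_addr], sp,
               dendritic_delay = cfg$dendritic_delay_ms)
    history_record(h, slot, win_addr, stats::setNames(list(win_times), win_addr))
    ws <- if (slot <= length(h$winners) && !is.null(h$winners[[slot]]))
      h$winners[[slot]] else character(0)
    ws[[subnet]] <- win_addr
    h$winners[[slot]] <- ws
    layer_times <- raster$times
    names(layer_times) <- addr_mem(subnet, slot, names(layer_times))
    slot_times <- c(slot_times, layer_times)
  }
  history_record(h, slot, know_addrs, know_times)
  out <- list(times = slot_times, window_ms = cfg$slot_learn_ms, dt = cfg$dt)
  class(out) <- "sm_raster"
  invisible(out)
}

#' Learn one labelled piece
#'
#' Runs the full learning procedure for a piece: the genre, composer and
#' title neurons stay active throughout (one knowledge slot per note), and
#' the melody notes are presented slot by slot to the memory network via
#' [present_note()]. After learning, consecutive notes are linked by
#' strictly positive delayed weights in both subnetworks, and every visited
#' winner carries positive incoming knowledge weights plus a feedback
#' synapse to the title neuron.
#'
#' @param model A [melody_snn()] model; updated in place.
#' @param piece An [sm_piece()].
#' @return The model, invisibly.
#' @export
learn_track <- function(model, piece) {
  stopifnot(inherits(piece, "sm_piece"))
  mel <- piece$melody
  if (nrow(mel) == 0) stop("empty melody track", call. = FALSE)
  model$state$history <- new_history()
  labels <- list(genre = piece$genre, composer = piece$composer,
                 title = piece$title)
  for (s in seq_len(nrow(mel))) {
    know <- activate_labels(model, labels, "learning")
    present_note(model, note(mel$pitch[s], mel$duration[s]), s, know)
  }
  model$state$n_layers <- max(model$state$n_layers, nrow(mel))
  model$state$pieces <- rbind(model$state$pieces, data.frame(
    title = piece$title, composer = piece$composer, genre = piece$genre,
    n_notes = nrow(mel), first_pitch = mel$pitch[1],
    first_duration = mel$duration[1], stringsAsFactors = FALSE))
  invisible(model)
}
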