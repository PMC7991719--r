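# ---- style-cued melody generation ------------------------------------------

#' Style cue for composition
#'
#' @param level `"genre"` or `"composer"`.
#' @param label Label string registered in the corresponding cluster.
#' @return A list of class `sm_style_cue`.
#' @examples
#' style_cue("genre", "classical")
#' style_cue("composer:Mozart")
#' @export
style_cue <- function(level, label = NULL) {
  if (is.null(label)) {  # accept "genre:classical" shorthand
    parts <- strsplit(level, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("cue must be level:label", call. = FALSE)
    label <- paste(parts[-1], collapse = ":")
    level <- parts[1]
  }
  level <- match.arg(level, c("genre", "composer"))
  stopifnot(nzchar(label))
  structure(list(level = level, label = label), class = "sm_style_cue")
}

#' Pick the winning column of a layer's slot raster
#'
#' The column with the earliest spike wins; ties are broken by the higher
#' spike count within the slot, then by the lower column index. An empty
#' raster signals a dead end (no learned continuation).
#'
#' @param raster An `sm_raster` whose entries are named by column index.
#' @return The winning column index (integer).
#' @export
select_winner <- function(raster) {
  times <- if (inherits(raster, "sm_raster")) raster$times else raster
  times <- times[lengths(times) > 0]
  if (!length(times)) {
    stop(structure(class = c("sm_dead_end", "error", "condition"),
                   list(message = "no column spiked (dead end)",
                        call = sys.call(-1))))
  }
  first <- vapply(times, min, numeric(1))
  counts <- lengths(times)
  cols <- as.integer(names(times))
  ord <- order(first, -counts, cols)
  cols[ord[1]]
}

#' Compose a melody in a requested style
#'
#' Generates a melody of `length` notes from seed notes, cued by a learned
#' genre or composer. The cue neuron is driven at the composition current
#' and fires in the gamma band for the whole run; the interneuron gate
#' silences the knowledge clusters that do not belong to the cue's circuit.
#' Seed notes are presented slot by slot as external tuning drive. For each
#' following slot, candidate columns receive their slot-delayed memory
#' input from previously active winners plus the cue cluster's learned
#' input; the normalized drive is simulated in the gamma band and the first
#' column to spike wins and silences its layer. The winning pitch and
#' duration columns decode to the next note, which conditions all later
#' slots. A slot in which no column receives positive drive is a dead end
#' and raises an error naming the slot, unless `greedy_restart` is set, in
#' which case the sequence is re-seeded from the last emitted note.
#'
#' @param model A fitted [melody_snn()] model.
#' @param cue An [style_cue()] (or `"genre:classical"` shorthand).
#' @param seeds Seed notes: an `sm_piece` melody data.frame, a list of
#'   [note()] objects, or a single note. At least one, fewer than `length`.
#' @param length Total number of notes requested (seeds included).
#' @param greedy_restart On a dead end, restart the layer pointer from the
#'   last emitted note instead of failing.
#' @param keep_rasters Keep per-slot diagnostic rasters in the result.
#' @return An object of class `sm_melody`: a list with `notes` (data.frame
#'   `pitch`, `duration`, `provenance`), `cue`, `slot_ms`, and
#'   (optionally) `rasters` and `knowledge` diagnostics.
#' @export
compose <- function(model, cue, seeds, length, greedy_restart = FALSE,
                    keep_rasters = TRUE) {
  stopifnot(inherits(model, "melody_snn"))
  if (is.character(cue)) cue <- style_cue(cue)
  stopifnot(inherits(cue, "sm_style_cue"))
  seeds <- as_melody_df(seeds)
  n_seed <- nrow(seeds)
  if (n_seed < 1 || n_seed >= length) {
    stop("need 1 <= seed count < length", call. = FALSE)
  }
  cfg <- model$config
  lookup <- activate_labels(model, stats::setNames(list(cue$label), cue$level),
                            phase = "composition")
  cue_addr <- lookup$addresses[[cue$level]]
  gate <- interneuron_gate(model, cue$level, cue_addr)
  nrm <- band_normalizer("gamma", model$cal$i_gamma_rs, cfg$rel_threshold,
                         cfg$contrast)
  cue_current <- normalize_drive(
    stats::setNames(cfg$know_current_compose, cue_addr), nrm,
    x_ref = cfg$know_current_compose)
  cue_raster <- simulate_window(cue_current, model$params$RS,
                                cfg$slot_compose_ms, cfg$dt)
  gated_raster <- gated_cluster_raster(model, gate, cue_addr)
  # knowledge neurons outside the cue's circuit receive no external drive;
  # simulate them with their (zero or feedforward-free) input so their
  # silence is an observed outcome, not an assumption
  silent_addrs <- setdiff(
    c(unname(model$reg$genre), unname(model$reg$composer),
      unname(model$reg$title)),
    c(cue_addr, gate$suppressed))
  silent_raster <- if (length(silent_addrs)) {
    tab <- model$store$tab
    ff <- vapply(silent_addrs, function(a)
      sum(tab$weight[tab$post == a & tab$sign == "exc" & tab$pre == cue_addr]),
      numeric(1))
    simulate_window(normalize_drive(ff, nrm), model$params$RS,
                    cfg$slot_compose_ms, cfg$dt)
  }

  h <- new_history()
  lp <- 0L  # layer pointer (decoupled from the output position on restart)
  notes <- data.frame(pitch = integer(0), duration = integer(0),
                      provenance = character(0))
  rasters <- list()

  run_layer <- function(lp, subnet, stim_col = NULL) {
    fired <- h$fired
    fired[[lp]] <- c(if (lp <= length(h$fired)) h$fired[[lp]] else
      character(0), cue_addr)
    drv <- layer_drive(model, subnet, lp,
                       stim_col = stim_col,
                       fired = if (is.null(stim_col)) fired else list())
    if (max(drv) <= 0) return(NULL)
    currents <- normalize_drive(drv, nrm)
    driven <- currents[currents > 0]
    simulate_window(driven, model$params$RS, cfg$slot_compose_ms, cfg$dt,
                    wta = TRUE, w_wta = model$cal$w_inh)
  }

  record_winner <- function(lp, win) {
    addrs <- c(addr_mem("P", lp, win$p_col), addr_mem("D", lp, win$d_col))
    times <- stats::setNames(
      list(win$p_raster$times[[as.character(win$p_col)]],
           win$d_raster$times[[as.character(win$d_col)]]), addrs)
    history_record(h, lp, c(addrs, cue_addr), times)
    h$winners[[lp]] <- c(P = addrs[1], D = addrs[2])
  }

  simulate_slot <- function(lp, stim = NULL) {
    stim_cols <- if (is.null(stim)) NULL else note_to_columns(stim)
    p_raster <- run_layer(lp, "P", stim_cols[["pitch"]])
    d_raster <- run_layer(lp, "D", stim_cols[["duration"]])
    if (is.null(p_raster) || is.null(d_raster)) return(NULL)
    list(p_col = select_winner(p_raster), d_col = select_winner(d_raster),
         p_raster = p_raster, d_raster = d_raster)
  }

  for (s in seq_len(length)) {
    lp <- lp + 1L
    if (s <= n_seed) {
      stim <- note(seeds$pitch[s], seeds$duration[s])
      win <- simulate_slot(lp, stim)
      prov <- "seed"
    } else {
      win <- simulate_slot(lp)
      if (is.null(win) && greedy_restart && nrow(notes) > 0) {
        # re-seed: restart the layer pointer from the last emitted note
        h <- new_history()
        lp <- 1L
        last <- note(notes$pitch[nrow(notes)], notes$duration[nrow(notes)])
        restart <- simulate_slot(lp, last)
        record_winner(lp, restart)
        lp <- 2L
        win <- simulate_slot(lp)
      }
      if (is.null(win)) {
        stop(structure(class = c("sm_dead_end", "error", "condition"),
          list(message = sprintf(
            "dead end at slot %d: no candidate column receives positive drive", s),
            call = NULL)))
      }
      prov <- "generated"
    }
    record_winner(lp, win)
    nxt <- columns_to_note(win$p_col, win$d_col)
    notes <- rbind(notes, data.frame(pitch = nxt$pitch,
                                     duration = nxt$duration,
                                     provenance = prov))
    if (keep_rasters) rasters[[s]] <- list(P = win$p_raster, D = win$d_raster)
  }

  out <- list(notes = notes, cue = cue, slot_ms = cfg$slot_compose_ms)
  if (keep_rasters) {
    out$rasters <- rasters
    out$knowledge <- list(cue = cue_raster, pool = gate$pool_raster,
                          gated = gated_raster, silent = silent_raster)
  }
  class(out) <- "sm_melody"
  out
}

as_melody_df <- function(x) {
  if (inherits(x, "sm_piece")) return(x$melody)
  if (inherits(x, "sm_melody")) return(x$notes[, c("pitch", "duration")])
  if (inherits(x, "sm_note")) x <- list(x)
  if (is.data.frame(x)) {
    stopifnot(all(c("pitch", "duration") %in% names(x)))
    return(x)
  }
  data.frame(pitch = vapply(x, `[[`, numeric(1), "pitch"),
             duration = vapply(x, `[[`, numeric(1), "duration"))
}

#' @export
print.sm_melody <- function(x, ...) {
  cat(sprintf("<sm_melody> %d notes cued by %s \"%s\"\n", nrow(x$notes),
              x$cue$level, x$cue$label))
  print(note_list(x))
  invisible(x)
}

#' Plain-text note list of a melody
#'
#' @param x An `sm_melody` (or `sm_piece`).
#' @return A data.frame with `pitch_name`, `midi_index`, `ticks` (and
#'   `provenance` for generated melodies).
#' @export
note_list <- function(x) {
  notes <- if (inherits(x, "sm_piece")) x$melody else x$notes
  out <- data.frame(pitch_name = pitch_to_name(notes$pitch),
                    midi_index = notes$pitch, ticks = notes$duration)
  if (!is.null(notes$provenance)) out$provenance <- notes$provenance
  out
}

#' Piano-roll plot of a melody
#'
#' @param x An `sm_melody`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sm_melody <- function(x, ...) {
  notes <- x$notes
  starts <- cumsum(c(0, notes$duration))[seq_len(nrow(notes))]
  graphics::plot(NA, xlim = c(0, sum(notes$duration)),
                 ylim = range(notes$pitch) + c(-1, 1),
                 xlab = "time (ticks)", ylab = "MIDI pitch", ...)
  col <- ifelse(notes$provenance == "seed", "grey50", "steelblue")
  graphics::rect(starts, notes$pitch - 0.4, starts + notes$duration,
                 notes$pitch + 0.4, col = col, border = "black")
  invisible(x)
}
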