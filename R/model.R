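#' Fit a spiking melody network to a labelled corpus
#'
#' Builds the full network -- pitch and duration memory subnetworks,
#' genre/composer/title knowledge clusters, fast-spiking interneuron pool
#' -- calibrates the theta and gamma drive currents for the configured
#' bands, and learns every piece of the corpus in order with STDP. Learning
#' happens in the theta band (4-8 Hz); the same learned weights are reused
#' in the gamma band (30-80 Hz) during composition, only the current
#' normalizer changes.
#'
#' @param corpus A list of [sm_piece()] objects (or a single piece).
#' @param config An [sm_config()].
#' @param quiet Suppress per-piece progress messages.
#' @return An object of class `melody_snn` with components:
#'   \describe{
#'     \item{config}{the configuration used}
#'     \item{cal}{calibrated currents and fixed inhibitory weights}
#'     \item{grids}{pitch and duration preference grids}
#'     \item{store}{the [synapse_store()]}
#'     \item{reg}{knowledge registries (label to neuron address)}
#'     \item{state}{layer count and learned-piece metadata}
#'   }
#' @examples
#' \donttest{
#' fit <- melody_snn(k545_prefix())
#' summary(fit)
#' }
#' @export
melody_snn <- function(corpus, config = sm_config(), quiet = TRUE) {
  if (inherits(corpus, "sm_piece")) corpus <- list(corpus)
  stopifnot(length(corpus) >= 1,
            all(vapply(corpus, inherits, logical(1), "sm_piece")))
  model <- new_melody_snn(config)
  for (piece in corpus) {
    n_before <- nrow(model$store$tab)
    learn_track(model, piece)
    if (!quiet) {
      message(sprintf("learned \"%s\" (%s, %s): %d notes, %d new synapses",
                      piece$title, piece$composer, piece$genre,
                      nrow(piece$melody), nrow(model$store$tab) - n_before))
    }
  }
  model
}

# empty, calibrated network with no learned pieces
new_melody_snn <- function(config = sm_config()) {
  rs <- izh_params("RS")
  fs <- izh_params("FS")
  i_theta_rs <- calibrate_band_current(rs, config$theta_hz,
                                       window_ms = config$slot_learn_ms,
                                       dt = config$dt)
  i_gamma_rs <- calibrate_band_current(rs, config$gamma_hz,
                                       window_ms = config$slot_compose_ms,
                                       dt = config$dt)
  i_gamma_fs <- calibrate_band_current(fs, config$gamma_hz,
                                       window_ms = config$slot_compose_ms,
                                       dt = config$dt)
  cal <- list(
    i_theta_rs = i_theta_rs,
    i_gamma_rs = i_gamma_rs,
    i_gamma_fs = i_gamma_fs,
    # fixed inhibitory weight: twice the drive that keeps a gamma-driven RS
    # neuron firing, so one active inhibitory source silences its target
    w_inh = 2 * i_gamma_rs,
    w_pool_in = 5
  )
  reg <- new.env(parent = emptyenv())
  reg$genre <- character(0)
  reg$composer <- character(0)
  reg$title <- character(0)
  state <- new.env(parent = emptyenv())
  state$n_layers <- 0L
  state$pieces <- data.frame(
    title = character(0), composer = character(0), genre = character(0),
    n_notes = integer(0), first_pitch = integer(0),
    first_duration = integer(0), stringsAsFactors = FALSE)
  state$history <- NULL
  structure(list(
    config = config,
    cal = cal,
    params = list(RS = rs, FS = fs),
    grids = list(
      pitch = pitch_grid(config$sigma, lam = config$sigma * i_theta_rs),
      duration = duration_grid(config$sigma, lam = config$sigma * i_theta_rs)),
    store = synapse_store(),
    reg = reg,
    state = state
  ), class = "melody_snn")
}

#' @export
print.melody_snn <- function(x, ...) {
  cat("Spiking melody network\n")
  cat(sprintf("  pieces learned: %d | memory layers: %d\n",
              nrow(x$state$pieces), x$state$n_layers))
  cat(sprintf("  knowledge: %d genres, %d composers, %d titles | %d interneurons\n",
              length(x$reg$genre), length(x$reg$composer),
              length(x$reg$title), x$config$n_interneurons))
  tab <- x$store$tab
  cat(sprintf("  synapses: %d (%d plastic) | plastic weights in [%.3g, %.3g]\n",
              nrow(tab), sum(tab$plastic),
              if (any(tab$plastic)) min(tab$weight[tab$plastic]) else 0,
              if (any(tab$plastic)) max(tab$weight[tab$plastic]) else 0))
  cat(sprintf("  bands: theta %g Hz at I = %.3g | gamma %g Hz at I = %.3g (RS)\n",
              x$config$theta_hz, x$cal$i_theta_rs,
              x$config$gamma_hz, x$cal$i_gamma_rs))
  invisible(x)
}

#' @export
summary.melody_snn <- function(object, ...) {
  tab <- object$store$tab
  kinds <- synapse_kind(tab$pre, tab$post)
  out <- list(
    n_pieces = nrow(object$state$pieces),
    pieces = object$state$pieces,
    n_layers = object$state$n_layers,
    clusters = c(genre = length(object$reg$genre),
                 composer = length(object$reg$composer),
                 title = length(object$reg$title)),
    synapse_counts = table(kinds),
    weight_summary = if (any(tab$plastic)) summary(tab$weight[tab$plastic]),
    cal = object$cal,
    config_hash = config_hash(object$config))
  class(out) <- "summary.melody_snn"
  out
}

#' @export
print.summary.melody_snn <- function(x, ...) {
  cat("Spiking melody network --", x$n_pieces, "pieces,",
      x$n_layers, "memory layers\n")
  cat("Knowledge neurons:", paste(names(x$clusters), x$clusters,
                                  collapse = ", "), "\n")
  cat("Synapses by kind:\n")
  print(x$synapse_counts)
  if (!is.null(x$weight_summary)) {
    cat("Plastic weights:\n")
    print(x$weight_summary)
  }
  cat("Config hash:", x$config_hash, "\n")
  invisible(x)
}

# coarse classification of a synapse by its endpoint address prefixes
synapse_kind <- function(pre, post) {
  pfx <- function(a) substr(a, 1, 1)
  paste0(pfx(pre), "->", pfx(post))
}

#' @export
coef.melody_snn <- function(object, ...) {
  synapse_table(object$store)
}

#' Predict method: compose a melody from a fitted network
#'
#' A thin wrapper around [compose()] using the modelling-verb interface.
#'
#' @param object A `melody_snn`.
#' @param cue,seeds,length,... Passed to [compose()].
#' @return An `sm_melody`.
#' @export
predict.melody_snn <- function(object, cue, seeds, length, ...) {
  compose(object, cue, seeds, length, ...)
}

#' Simulate melodies from a fitted network
#'
#' Draws `nsim` melodies by picking a learned piece consistent with the cue
#' uniformly at random, seeding the composition with that piece's opening
#' note. With a fixed `seed` the draw -- and hence the whole output -- is
#' reproducible; the network dynamics themselves are deterministic.
#'
#' @param object A `melody_snn`.
#' @param nsim Number of melodies.
#' @param seed Optional integer seed.
#' @param cue An [style_cue()] or `"level:label"` string.
#' @param length Notes per melody (defaults to the seed piece's length).
#' @param ... Passed to [compose()].
#' @return A list of `sm_melody` objects.
#' @export
simulate.melody_snn <- function(object, nsim = 1, seed = NULL, cue,
                                length = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(cue)) cue <- style_cue(cue)
  meta <- object$state$pieces
  pool <- if (cue$level == "genre") meta[meta$genre == cue$label, ]
          else meta[meta$composer == cue$label, ]
  if (nrow(pool) == 0) {
    stop(sprintf("no learned piece matches %s \"%s\"", cue$level, cue$label),
         call. = FALSE)
  }
  lapply(seq_len(nsim), function(i) {
    row <- pool[sample.int(nrow(pool), 1), ]
    compose(object, cue,
            seeds = data.frame(pitch = row$first_pitch,
                               duration = row$first_duration),
            length = if (is.null(length)) row$n_notes else length, ...)
  })
}

#' Weight-structure plot of a fitted network
#'
#' Shows the learned inter-layer weights of one memory subnetwork as an
#' image over (presynaptic layer, postsynaptic layer) aggregated by
#' maximum weight, a compact view of how far sequential context reaches.
#'
#' @param x A `melody_snn`.
#' @param subnet `"pitch"` or `"duration"`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.melody_snn <- function(x, subnet = c("pitch", "duration"), ...) {
  subnet <- match.arg(subnet)
  pfx <- if (subnet == "pitch") "P:" else "D:"
  tab <- x$store$tab
  mem <- tab[startsWith(tab$pre, pfx) & startsWith(tab$post, pfx) &
               tab$plastic, ]
  n <- max(1L, x$state$n_layers)
  m <- matrix(0, n, n)
  if (nrow(mem)) {
    lay <- function(a) as.integer(sub("^[PD]:([0-9]+):.*$", "\\1", a))
    for (i in seq_len(nrow(mem))) {
      r <- lay(mem$pre[i]); cc <- lay(mem$post[i])
      m[r, cc] <- max(m[r, cc], mem$weight[i])
    }
  }
  graphics::image(seq_len(n), seq_len(n), m, xlab = "presynaptic layer",
                  ylab = "postsynaptic layer",
                  main = sprintf("%s subnetwork inter-layer weights", subnet),
                  ...)
  invisible(x)
}
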