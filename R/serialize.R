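# ---- model archive: gzip-compressed JSON, exact weight round-trip ----------

#' Write a fitted network to a model archive
#'
#' Serializes the whole model -- configuration, calibrated currents, the
#' flat synapse table `(pre, post, weight, delay_slots, sign, plastic)`,
#' knowledge registries and learned-piece metadata -- as gzip-compressed
#' JSON with full floating-point precision, stamped with the config hash.
#' Writing the same model twice produces byte-identical archives, and
#' [read_melody_snn()] restores an exactly equivalent model (weights
#' round-trip exactly).
#'
#' @param model A [melody_snn()] model.
#' @param path Output file path (conventionally `.smz`).
#' @return `path`, invisibly.
#' @export
write_melody_snn <- function(model, path) {
  stopifnot(inherits(model, "melody_snn"))
  payload <- list(
    format = "spikemelody-model",
    version = 1L,
    config = unclass(model$config),
    config_hash = config_hash(model$config),
    cal = model$cal,
    registry = list(genre = as.list(model$reg$genre),
                    composer = as.list(model$reg$composer),
                    title = as.list(model$reg$title)),
    n_layers = model$state$n_layers,
    pieces = model$state$pieces,
    synapses = synapse_table(model$store))
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                           dataframe = "columns", null = "null")
  con <- gzfile(path, "wb", compression = 9)
  on.exit(close(con))
  writeBin(charToRaw(as.character(json)), con)
  invisible(path)
}

#' Read a model archive
#'
#' @param path Path written by [write_melody_snn()].
#' @return A `melody_snn` model equivalent to the one written (the
#'   calibrated currents are restored, not recalibrated).
#' @export
read_melody_snn <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, what = "raw", n = 64 * 1024^2)
  payload <- jsonlite::fromJSON(rawToChar(raw), simplifyVector = TRUE)
  if (!identical(payload$format, "spikemelody-model")) {
    stop("not a spikemelody model archive: ", path, call. = FALSE)
  }
  cfg <- do.call(sm_config, payload$config)
  model <- structure(list(
    config = cfg,
    cal = payload$cal,
    params = list(RS = izh_params("RS"), FS = izh_params("FS")),
    grids = list(
      pitch = pitch_grid(cfg$sigma, lam = cfg$sigma * payload$cal$i_theta_rs),
      duration = duration_grid(cfg$sigma,
                               lam = cfg$sigma * payload$cal$i_theta_rs)),
    store = synapse_store(),
    reg = new.env(parent = emptyenv()),
    state = new.env(parent = emptyenv())
  ), class = "melody_snn")
  for (level in c("genre", "composer", "title")) {
    v <- unlist(payload$registry[[level]])
    model$reg[[level]] <- if (is.null(v)) character(0) else v
  }
  syn <- payload$synapses
  if (length(syn) && nrow(as.data.frame(syn))) {
    tab <- data.table::as.data.table(syn)
    tab$delay_slots <- as.integer(tab$delay_slots)
    data.table::setkeyv(tab, c("pre", "post"))
    model$store$tab <- tab
  }
  model$state$n_layers <- as.integer(payload$n_layers)
  pieces <- as.data.frame(payload$pieces)
  if (!nrow(pieces)) {
    pieces <- data.frame(title = character(0), composer = character(0),
                         genre = character(0), n_notes = integer(0),
                         first_pitch = integer(0), first_duration = integer(0))
  }
  model$state$pieces <- pieces
  model$state$history <- NULL
  model
}
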