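# ---- standard MIDI file I/O ------------------------------------------------
# Minimal SMF (format 0/1) support: note events only. Written from scratch
# because melodies here are plain monophonic note lists; tempo, dynamics,
# pedal and program changes are ignored on read and omitted on write.

# big-endian unsigned integer from raw bytes
be_int <- function(bytes) {
  sum(as.numeric(bytes) * 256^(rev(seq_along(bytes)) - 1))
}

int_be <- function(x, width) {
  as.raw((x %/% 256^(rev(seq_len(width)) - 1)) %% 256)
}

# variable-length quantity encoding used for delta times
encode_varlen <- function(x) {
  stopifnot(x >= 0)
  out <- as.raw(x %% 128)
  x <- x %/% 128
  while (x > 0) {
    out <- c(as.raw(128 + x %% 128), out)
    x <- x %/% 128
  }
  out
}

# reader state: raw vector + cursor held in an environment
decode_varlen <- function(bytes, pos) {
  val <- 0
  repeat {
    b <- as.integer(bytes[pos])
    pos <- pos + 1
    val <- val * 128 + (b %% 128)
    if (b < 128) break
  }
  list(value = val, pos = pos)
}

#' Read a standard MIDI file into a labelled piece
#'
#' Parses a format 0 or 1 standard MIDI file, rescales its tick resolution
#' to 480 ticks per crotchet, extracts the melody track (the first track
#' containing note events), reduces simultaneous notes to the highest
#' pitch, converts note-on/note-off spans to durations quantized on the
#' 60-tick grid, and drops the gaps between notes (a note's duration is its
#' sounding span; rests are not modelled).
#'
#' @param path Path to a `.mid` file.
#' @param title,composer,genre Labels for the piece; default to the file
#'   name and `"Unknown"`.
#' @return An [sm_piece()].
#' @export
read_midi <- function(path, title = NULL, composer = "Unknown",
                      genre = "Unknown") {
  bytes <- readBin(path, what = "raw", n = file.info(path)$size)
  if (length(bytes) < 14 || rawToChar(bytes[1:4]) != "MThd") {
    stop("not a standard MIDI file: ", path, call. = FALSE)
  }
  division <- be_int(bytes[13:14])
  if (division >= 32768) {
    stop("SMPTE time division is not supported", call. = FALSE)
  }
  n_tracks <- be_int(bytes[11:12])
  pos <- 15
  spans <- NULL
  for (trk in seq_len(n_tracks)) {
    if (pos + 7 > length(bytes) || rawToChar(bytes[pos:(pos + 3)]) != "MTrk") {
      stop("corrupt MIDI track header", call. = FALSE)
    }
    track_len <- be_int(bytes[(pos + 4):(pos + 7)])
    pos <- pos + 8
    end <- pos + track_len
    spans <- parse_track_notes(bytes, pos, end)
    pos <- end
    if (!is.null(spans) && nrow(spans) > 0) break  # first track with notes
  }
  if (is.null(spans) || nrow(spans) == 0) {
    stop("no note events found in ", path, call. = FALSE)
  }
  scale <- 480 / division
  spans$start <- spans$start * scale
  spans$end <- spans$end * scale
  # simultaneous onsets reduce to the highest pitch (melody-line heuristic)
  spans <- spans[order(spans$start, -spans$pitch), ]
  spans <- spans[!duplicated(spans$start), ]
  melody <- data.frame(
    pitch = spans$pitch,
    duration = quantize_duration(pmax(spans$end - spans$start, 1)))
  if (is.null(title)) title <- tools::file_path_sans_ext(basename(path))
  sm_piece(genre, composer, title, melody, source_path = path)
}

# note-on/off pairing within one track; returns start/end/pitch in raw ticks
parse_track_notes <- function(bytes, pos, end) {
  t <- 0
  status <- 0L
  active <- list()  # pitch -> vector of start times (FIFO)
  starts <- numeric(0); ends <- numeric(0); pitches <- integer(0)
  while (pos < end) {
    d <- decode_varlen(bytes, pos)
    t <- t + d$value
    pos <- d$pos
    b <- as.integer(bytes[pos])
    if (b >= 128) {
      status <- b
      pos <- pos + 1
    }  # else: running status, reuse previous
    hi <- status %/% 16
    if (status == 255) {           # meta event
      type <- as.integer(bytes[pos]); pos <- pos + 1
      len <- decode_varlen(bytes, pos)
      pos <- len$pos + len$value
      if (type == 47) break        # end of track
    } else if (status %in% c(240, 247)) {  # sysex
      len <- decode_varlen(bytes, pos)
      pos <- len$pos + len$value
    } else if (hi %in% c(8, 9)) {  # note off / note on
      pitch <- as.integer(bytes[pos])
      vel <- as.integer(bytes[pos + 1])
      pos <- pos + 2
      key <- as.character(pitch)
      if (hi == 9 && vel > 0) {
        active[[key]] <- c(active[[key]], t)
      } else if (length(active[[key]])) {
        starts <- c(starts, active[[key]][1])
        ends <- c(ends, t)
        pitches <- c(pitches, pitch)
        active[[key]] <- active[[key]][-1]
      }
    } else if (hi %in% c(10, 11, 14)) {  # 2-byte channel messages
      pos <- pos + 2
    } else if (hi %in% c(12, 13)) {      # 1-byte channel messages
      pos <- pos + 1
    } else {
      stop("unparseable MIDI event (status ", status, ")", call. = FALSE)
    }
  }
  if (!length(starts)) return(NULL)
  data.frame(start = starts, end = ends, pitch = pitches)
}

#' Write a melody as a standard MIDI file
#'
#' Writes a format 0 file at 480 ticks per crotchet with one melody track
#' of back-to-back notes. On the 60-tick grid, [read_midi()] recovers the
#' written note sequence exactly.
#'
#' @param x An `sm_melody`, [sm_piece()], or data.frame with `pitch` and
#'   `duration` columns.
#' @param path Output path.
#' @param velocity Note-on velocity (1-127).
#' @return `path`, invisibly.
#' @export
write_midi <- function(x, path, velocity = 80) {
  notes <- as_melody_df(x)
  if (nrow(notes) == 0) stop("refusing to write an empty melody", call. = FALSE)
  ev <- raw(0)
  for (i in seq_len(nrow(notes))) {
    p <- as.integer(notes$pitch[i])
    d <- as.integer(notes$duration[i])
    ev <- c(ev,
            encode_varlen(0), as.raw(c(0x90, p, velocity)),
            encode_varlen(d), as.raw(c(0x80, p, 0)))
  }
  ev <- c(ev, encode_varlen(0), as.raw(c(0xFF, 0x2F, 0x00)))
  track <- c(charToRaw("MTrk"), int_be(length(ev), 4), ev)
  header <- c(charToRaw("MThd"), int_be(6, 4), int_be(0, 2), int_be(1, 2),
              int_be(480, 2))
  writeBin(c(header, track), path)
  invisible(path)
}

#' Read a corpus metadata table
#'
#' Comma-delimited UTF-8 text with a header row naming the columns
#' `path`, `title`, `composer`, `genre` -- one row per piece. Relative
#' paths are resolved against `dir`.
#'
#' @param metadata_path Path to the metadata file.
#' @param dir Base directory for relative MIDI paths.
#' @return A data.frame with the four columns, paths resolved.
#' @export
read_corpus_metadata <- function(metadata_path, dir = dirname(metadata_path)) {
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("path", "title", "composer", "genre")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  rel <- !file.exists(meta$path)
  meta$path[rel] <- file.path(dir, meta$path[rel])
  meta
}

#' Read a corpus of MIDI files described by a metadata table
#'
#' @param metadata_path,dir See [read_corpus_metadata()].
#' @return A list of [sm_piece()] objects in metadata order.
#' @export
read_corpus <- function(metadata_path, dir = dirname(metadata_path)) {
  meta <- read_corpus_metadata(metadata_path, dir)
  lapply(seq_len(nrow(meta)), function(i) {
    if (!file.exists(meta$path[i])) {
      stop("missing MIDI file: ", meta$path[i], call. = FALSE)
    }
    read_midi(meta$path[i], title = meta$title[i],
              composer = meta$composer[i], genre = meta$genre[i])
  })
}

#' Export a corpus of pieces as MIDI files plus a metadata table
#'
#' @param pieces List of [sm_piece()] objects.
#' @param dir Output directory (created if needed).
#' @return The metadata file path, invisibly.
#' @export
write_corpus <- function(pieces, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(pieces), function(i) {
    p <- pieces[[i]]
    fn <- sprintf("piece_%03d.mid", i)
    write_midi(p$melody, file.path(dir, fn))
    data.frame(path = fn, title = p$title, composer = p$composer,
               genre = p$genre, stringsAsFactors = FALSE)
  })
  meta_path <- file.path(dir, "metadata.csv")
  utils::write.csv(do.call(rbind, rows), meta_path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(meta_path)
}
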