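#' Construct a labelled musical piece
#'
#' @param genre,composer,title Non-empty label strings.
#' @param melody A data.frame with integer columns `pitch` (0-127) and
#'   `duration` (multiples of 60 ticks), one row per note in order; or a
#'   list of [note()] objects.
#' @param source_path Optional path of the MIDI file the piece came from.
#' @return An object of class `sm_piece`.
#' @export
sm_piece <- function(genre, composer, title, melody, source_path = NA_character_) {
  stopifnot(nzchar(genre), nzchar(composer), nzchar(title))
  if (is.list(melody) && !is.data.frame(melody)) {
    melody <- data.frame(
      pitch = vapply(melody, `[[`, numeric(1), "pitch"),
      duration = vapply(melody, `[[`, numeric(1), "duration"))
  }
  if (nrow(melody) == 0) stop("piece has an empty melody", call. = FALSE)
  # validate every note against the grid
  for (i in seq_len(nrow(melody))) note(melody$pitch[i], melody$duration[i])
  melody$pitch <- as.integer(melody$pitch)
  melody$duration <- as.integer(melody$duration)
  structure(list(genre = genre, composer = composer, title = title,
                 melody = melody, source_path = source_path),
            class = "sm_piece")
}

#' @export
print.sm_piece <- function(x, ...) {
  cat(sprintf("<sm_piece> \"%s\" by %s (%s): %d notes\n",
              x$title, x$composer, x$genre, nrow(x$melody)))
  head_n <- utils::head(x$melody, 8)
  cat(" ", paste0("n(", pitch_to_name(head_n$pitch), ",", head_n$duration, ")",
                  collapse = " "),
      if (nrow(x$melody) > 8) "..." else "", "\n")
  invisible(x)
}

#' Synthetic corpus specification
#'
#' @param n_pieces Number of pieces to generate.
#' @param notes_per_piece Notes in each piece.
#' @param genres,composers Label sets; composers are assigned to genres
#'   round-robin.
#' @param disjoint_ranges If `TRUE`, each composer walks inside a private
#'   pitch range and draws durations from a private window of the duration
#'   grid, so that neither pitch nor duration bigrams can be shared across
#'   composers (both memory subnetworks stay interference-free).
#' @param seed Integer seed; identical spec and seed give an identical
#'   corpus.
#' @return A list of class `sm_fixture_spec`.
#' @export
fixture_spec <- function(n_pieces = 4, notes_per_piece = 10,
                         genres = c("classical", "romantic"),
                         composers = c("Mozart", "Haydn", "Chopin", "Liszt"),
                         disjoint_ranges = TRUE, seed = 1L) {
  stopifnot(n_pieces >= 1, notes_per_piece >= 1,
            length(genres) >= 1, length(composers) >= 1)
  structure(list(n_pieces = n_pieces, notes_per_piece = notes_per_piece,
                 genres = genres, composers = composers,
                 disjoint_ranges = disjoint_ranges, seed = as.integer(seed)),
            class = "sm_fixture_spec")
}

#' Three-note sonata opening fixture
#'
#' The canonical worked example used throughout the documentation: the
#' opening of Mozart's Sonata No. 16 in C major (K545) reduced to its first
#' three melody notes, `(C5, 960)`, `(E5, 480)`, `(G5, 480)`, labelled
#' Classical / Mozart / K545. C5 is MIDI index 72.
#'
#' @return An `sm_piece` with three notes.
#' @examples
#' k545_prefix()
#' @export
k545_prefix <- function() {
  sm_piece("Classical", "Mozart", "K545",
           data.frame(pitch = c(72L, 76L, 79L),
                      duration = c(960L, 480L, 480L)))
}

#' Two-piece shared-prefix competition fixture
#'
#' Two four-note pieces that open with the same two notes,
#' `n(A5, 240)` and `n(E4, 120)`, then diverge: the classical piece
#' continues `(C4, 240), (D4, 120)` while the romantic piece repeats its
#' prefix `(A5, 240), (E4, 120)`. Seeding a composition with the shared
#' prefix forces the genre cue to resolve the continuation, which makes
#' this the standard test of knowledge-biased competition. The romantic
#' continuation beyond the divergence point is a fixture convention
#' (repeat-prefix), chosen minimally.
#'
#' @return A list of two `sm_piece` objects named `classical` and
#'   `romantic`.
#' @examples
#' shared_prefix_fixture()$classical
#' @export
shared_prefix_fixture <- function() {
  a5 <- name_to_pitch("A5"); e4 <- name_to_pitch("E4")
  c4 <- name_to_pitch("C4"); d4 <- name_to_pitch("D4")
  list(
    classical = sm_piece("classical", "Mozart", "Divergent Air (classical)",
      data.frame(pitch = c(a5, e4, c4, d4),
                 duration = c(240L, 120L, 240L, 120L))),
    romantic = sm_piece("romantic", "Chopin", "Divergent Air (romantic)",
      data.frame(pitch = c(a5, e4, a5, e4),
                 duration = c(240L, 120L, 240L, 120L)))
  )
}

#' Deterministic random-walk corpus
#'
#' Generates scale-constrained random-walk melodies on the 60-tick duration
#' grid. Each composer owns a contiguous pitch range (disjoint across
#' composers when `disjoint_ranges` is set, so no bigram can be shared) and
#' walks over the C-major scale degrees inside it; durations are drawn from
#' quaver/crotchet/minim values. The corpus is a pure function of the spec.
#'
#' @param spec An [fixture_spec()].
#' @return A list of `sm_piece` objects.
#' @examples
#' corpus <- random_walk_corpus(fixture_spec(n_pieces = 2, seed = 7))
#' length(corpus)
#' @export
random_walk_corpus <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "sm_fixture_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)
  n_comp <- length(spec$composers)
  major <- c(0L, 2L, 4L, 5L, 7L, 9L, 11L)
  pieces <- vector("list", spec$n_pieces)
  for (i in seq_len(spec$n_pieces)) {
    ci <- (i - 1L) %% n_comp + 1L
    composer <- spec$composers[ci]
    genre <- spec$genres[(ci - 1L) %% length(spec$genres) + 1L]
    if (spec$disjoint_ranges) {
      span <- 120 %/% n_comp
      lo <- 4L + (ci - 1L) * span        # private pitch range per composer
      scale_pitches <- lo + major[major < span]
      dspan <- max(1L, 64L %/% n_comp)   # private duration window
      dur_values <- (((ci - 1L) * dspan) + seq_len(min(dspan, 4L))) * 60L
    } else {
      scale_pitches <- 48L + major       # one shared octave
      dur_values <- c(120L, 240L, 480L, 960L)
    }
    k <- sample.int(length(scale_pitches), 1)
    pitches <- integer(spec$notes_per_piece)
    for (j in seq_len(spec$notes_per_piece)) {
      pitches[j] <- scale_pitches[k]
      step <- sample(c(-2L, -1L, 1L, 2L), 1)
      k <- min(max(k + step, 1L), length(scale_pitches))
    }
    durations <- dur_values[sample.int(length(dur_values),
                                       spec$notes_per_piece, replace = TRUE)]
    pieces[[i]] <- sm_piece(
      genre, composer, sprintf("%s walk no. %d", composer, i),
      data.frame(pitch = pitches, duration = durations))
  }
  pieces
}
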