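#' Construct and validate a note
#'
#' A note is a `(pitch, duration)` pair: a MIDI pitch index in 0-127 and a
#' duration in MIDI ticks on the 60-tick grid (60 to 3840 ticks at 480
#' ticks per crotchet).
#'
#' @param pitch Integer MIDI pitch index (0-127), or a scientific pitch
#'   name such as `"C4"` (middle C = C4 = 60).
#' @param duration Duration in ticks; must be a positive multiple of 60,
#'   at most 3840.
#' @return A list with integer fields `pitch` and `duration`, class
#'   `sm_note`.
#' @examples
#' note("C5", 960)
#' note(60, 480)
#' @export
note <- function(pitch, duration) {
  if (is.character(pitch)) pitch <- name_to_pitch(pitch)
  pitch <- as.integer(pitch)
  duration <- as.integer(duration)
  if (is.na(pitch) || pitch < 0 || pitch > 127) {
    stop("pitch must be a MIDI index in 0..127", call. = FALSE)
  }
  if (is.na(duration) || duration < 60 || duration > 3840 ||
      duration %% 60 != 0) {
    stop("duration must be a multiple of 60 ticks in 60..3840", call. = FALSE)
  }
  structure(list(pitch = pitch, duration = duration), class = "sm_note")
}

#' @export
print.sm_note <- function(x, ...) {
  cat(sprintf("n(%s = %d, %d ticks)\n", pitch_to_name(x$pitch), x$pitch,
              x$duration))
  invisible(x)
}

#' Gaussian tuning curve
#'
#' @param mu Preferred stimulus (column-index units).
#' @param sigma Tuning width (> 0), column-index units.
#' @param lam Gain constant; the peak response is `lam / sigma`.
#' @return A list of class `sm_tuning_curve`.
#' @export
tuning_curve <- function(mu, sigma = 1, lam = 1) {
  stopifnot(sigma > 0)
  structure(list(mu = mu, sigma = sigma, lam = lam),
            class = "sm_tuning_curve")
}

#' Tuning-curve response current
#'
#' `lam * (1/sigma) * exp(-(x - mu)^2 / sigma^2)`: maximal at the preferred
#' stimulus and symmetric about it.
#'
#' @param x Stimulus in column-index units (vectorized).
#' @param curve An [tuning_curve()] object.
#' @return Input current(s).
#' @examples
#' tc <- tuning_curve(mu = 60, sigma = 1, lam = 5)
#' tuning_current(60, tc)  # peak: lam / sigma
#' @export
tuning_current <- function(x, curve) {
  curve$lam * (1 / curve$sigma) * exp(-(x - curve$mu)^2 / curve$sigma^2)
}

#' Minicolumn preference grids
#'
#' The pitch grid has exactly 128 columns preferring MIDI pitch indices
#' 0..127; the duration grid has 64 columns preferring 60, 120, ..., 3840
#' ticks (constant 60-tick spacing). Stimulus distance is measured in
#' column-index units for both grids, so a single tuning width serves both.
#'
#' @param sigma Tuning width shared by all columns (column-index units).
#' @param lam Tuning gain; in a fitted network this is `sigma * i_cal` of
#'   the theta band so the peak tuning current equals the calibrated theta
#'   drive.
#' @return A list of class `sm_grid` with fields `kind`, `preferences`
#'   (preferred pitch indices or tick values) and `sigma`, `lam`.
#' @export
pitch_grid <- function(sigma = 1, lam = 1) {
  structure(list(kind = "pitch", preferences = 0:127,
                 sigma = sigma, lam = lam), class = "sm_grid")
}

#' @rdname pitch_grid
#' @export
duration_grid <- function(sigma = 1, lam = 1) {
  structure(list(kind = "duration", preferences = seq(60L, 3840L, by = 60L),
                 sigma = sigma, lam = lam), class = "sm_grid")
}

# drive over all columns of a grid for a stimulus given as a column index
grid_drive <- function(grid, stim_col) {
  cols <- seq_along(grid$preferences) - 1L
  curve <- tuning_curve(mu = stim_col, sigma = grid$sigma, lam = grid$lam)
  drv <- tuning_current(cols, curve)
  names(drv) <- as.character(cols)
  drv
}

#' External current for a knowledge-label stimulus
#'
#' A knowledge neuron receives a fixed current when the external label
#' matches its preference and nothing otherwise: 5 during learning (theta
#' drive) and 30 during composition (gamma drive).
#'
#' @param stimulus,preference Label strings (exact match).
#' @param phase `"learning"` or `"composition"`.
#' @param config Optional [sm_config()] supplying the two current levels.
#' @return A scalar current.
#' @examples
#' knowledge_current("Mozart", "Mozart", "learning")      # 5
#' knowledge_current("classical", "classical", "composition")  # 30
#' @export
knowledge_current <- function(stimulus, preference,
                              phase = c("learning", "composition"),
                              config = sm_config()) {
  phase <- match.arg(phase)
  if (!nzchar(stimulus)) stop("empty stimulus label", call. = FALSE)
  if (!identical(stimulus, preference)) return(0)
  if (phase == "learning") config$know_current_learn else
    config$know_current_compose
}

#' Map a note to its preferring grid columns
#'
#' @param x An [note()] (or a list with `pitch` and `duration` fields).
#' @return Named integer vector `c(pitch = , duration = )` of 0-based
#'   column indices: the pitch column equals the pitch index and the
#'   duration column is `duration/60 - 1`.
#' @examples
#' note_to_columns(note(60, 480))  # pitch 60, duration 7
#' @export
note_to_columns <- function(x) {
  if (x$duration %% 60 != 0) {
    stop("duration off the 60-tick grid; quantize first", call. = FALSE)
  }
  c(pitch = as.integer(x$pitch), duration = as.integer(x$duration / 60) - 1L)
}

# inverse of note_to_columns (0-based columns -> note)
columns_to_note <- function(pitch_col, duration_col) {
  note(pitch_col, (duration_col + 1L) * 60L)
}

#' Quantize a raw tick duration to the 60-tick grid
#'
#' Nearest multiple of 60, ties rounding up, clipped to `[60, 3840]`.
#'
#' @param raw_ticks Positive duration(s) in ticks.
#' @return Quantized duration(s).
#' @examples
#' quantize_duration(475)  # 480
#' quantize_duration(90)   # 120 (tie rounds up)
#' @export
quantize_duration <- function(raw_ticks) {
  stopifnot(all(raw_ticks > 0))
  q <- floor(raw_ticks / 60 + 0.5) * 60
  as.integer(pmin(pmax(q, 60), 3840))
}

NOTE_BASE <- c(C = 0L, D = 2L, E = 4L, F = 5L, G = 7L, A = 9L, B = 11L)

#' Convert between scientific pitch names and MIDI indices
#'
#' Scientific pitch notation with middle C = C4 = MIDI 60; sharps (`#`) and
#' flats (`b`) are accepted (`F#5`, `Bb3`). The printable name uses sharps.
#'
#' @param name Pitch name(s) such as `"C4"`, `"F#5"`, `"Bb3"`.
#' @return `name_to_pitch`: integer MIDI indices;
#'   `pitch_to_name`: character names.
#' @examples
#' name_to_pitch("C4")  # 60
#' name_to_pitch("C5")  # 72
#' pitch_to_name(61)    # "C#4"
#' @export
name_to_pitch <- function(name) {
  vapply(name, function(nm) {
    m <- regmatches(nm, regexec("^([A-Ga-g])([#b]?)(-?[0-9]+)$", nm))[[1]]
    if (length(m) == 0) stop("unparseable pitch name: ", nm, call. = FALSE)
    base <- NOTE_BASE[[toupper(m[2])]]
    acc <- switch(m[3], "#" = 1L, "b" = -1L, 0L)
    octave <- as.integer(m[4])
    p <- (octave + 1L) * 12L + base + acc
    if (p < 0 || p > 127) stop("pitch out of MIDI range: ", nm, call. = FALSE)
    p
  }, integer(1), USE.NAMES = FALSE)
}

#' @rdname name_to_pitch
#' @param pitch Integer MIDI pitch index (0-127), vectorized.
#' @export
pitch_to_name <- function(pitch) {
  names12 <- c("C", "C#", "D", "D#", "E", "F", "F#", "G", "G#", "A", "A#", "B")
  vapply(as.integer(pitch), function(p) {
    stopifnot(p >= 0, p <= 127)
    paste0(names12[p %% 12 + 1], p %/% 12 - 1)
  }, character(1))
}
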