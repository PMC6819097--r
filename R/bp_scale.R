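#' Bohlen-Pierce scale configuration
#'
#' The Bohlen-Pierce (BP) scale divides the tritave (a 3:1 frequency ratio,
#' the analogue of the octave) into 13 logarithmically even steps. Tones are
#' addressed by integer scale-degree indices `n` above a fundamental `k`,
#' with frequency `k * 3^(n/13)`. The signaling games use five fixed degrees
#' mapped to the five keyboard keys available to players.
#'
#' @param fundamental_k Fundamental frequency `k` in Hz. Must be positive.
#' @param steps_per_tritave Number of equal steps dividing the 3:1 tritave.
#' @param allowed_degrees Integer degrees permitted in game signals.
#' @return An object of class `bp_scale` (a list with the three fields).
#' @examples
#' sc <- bp_scale_config()
#' bp_frequency(sc$fundamental_k, 13) # one tritave up: 3 * 440
#' @export
bp_scale_config <- function(fundamental_k = 440,
                            steps_per_tritave = 13,
                            allowed_degrees = c(0L, 4L, 6L, 7L, 10L)) {
  if (!is.numeric(fundamental_k) || length(fundamental_k) != 1 ||
      !is.finite(fundamental_k) || fundamental_k <= 0) {
    stop("`fundamental_k` must be a single positive number (Hz)", call. = FALSE)
  }
  if (steps_per_tritave < 1) {
    stop("`steps_per_tritave` must be >= 1", call. = FALSE)
  }
  if (length(allowed_degrees) == 0) {
    stop("`allowed_degrees` must be non-empty", call. = FALSE)
  }
  structure(
    list(
      fundamental_k = fundamental_k,
      steps_per_tritave = as.integer(steps_per_tritave),
      allowed_degrees = sort(unique(as.integer(allowed_degrees)))
    ),
    class = "bp_scale"
  )
}

#' Frequency of a Bohlen-Pierce scale degree
#'
#' Evaluates `F = k * 3^(n / steps)` for integer step index `n` above the
#' fundamental `k`. With the standard 13-step tritave, degree 13 is exactly
#' three times the fundamental.
#'
#' @param k Fundamental frequency in Hz (positive scalar).
#' @param n Scale-degree index (vectorised; may be negative).
#' @param steps_per_tritave Steps per 3:1 tritave (default 13).
#' @return Frequency (or frequencies) in Hz.
#' @examples
#' bp_frequency(440, 6)  # ~730.6 Hz
#' @export
bp_frequency <- function(k, n, steps_per_tritave = 13) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k <= 0)) {
    stop("`k` must be positive and finite (Hz)", call. = FALSE)
  }
  k * 3^(n / steps_per_tritave)
}

#' Validate a game tone sequence
#'
#' A signal is an ordered vector of exactly five scale-degree indices. In
#' game mode every degree must come from the scale's allowed set (the five
#' keys available to players).
#'
#' @param degrees Integer vector of length 5.
#' @param scale A [bp_scale_config()] object.
#' @param game_mode If `TRUE`, enforce membership in `scale$allowed_degrees`.
#' @return The degrees, invisibly, as an integer vector.
#' @export
validate_tone_sequence <- function(degrees, scale = bp_scale_config(),
                                   game_mode = TRUE) {
  if (length(degrees) != 5 || any(is.na(degrees)) ||
      any(degrees != round(degrees))) {
    stop("a tone sequence is exactly 5 integer scale degrees", call. = FALSE)
  }
  degrees <- as.integer(degrees)
  if (game_mode && !all(degrees %in% scale$allowed_degrees)) {
    stop("degrees outside the scale's allowed set: ",
         paste(setdiff(degrees, scale$allowed_degrees), collapse = ", "),
         call. = FALSE)
  }
  invisible(degrees)
}

#' Frequencies of a tone sequence
#'
#' @param degrees Integer vector of 5 scale degrees.
#' @param scale A [bp_scale_config()] object supplying `k` and the tritave
#'   division.
#' @param game_mode Passed to [validate_tone_sequence()].
#' @return Numeric vector of 5 frequencies in Hz.
#' @examples
#' round(sequence_frequencies(c(0, 2, 3, 4, 6), game_mode = FALSE), 1)
#' @export
sequence_frequencies <- function(degrees, scale = bp_scale_config(),
                                 game_mode = FALSE) {
  degrees <- validate_tone_sequence(degrees, scale, game_mode = game_mode)
  bp_frequency(scale$fundamental_k, degrees, scale$steps_per_tritave)
}

#' Relative contour transform of a tone sequence
#'
#' Maps a five-tone sequence to the four directions of its successive
#' intervals: `+1` (up), `0` (repeat), `-1` (down). The repeat symbol is
#' needed because the seeding material includes a monotone (all-equal)
#' control signal, whose contour entropy must be 0 bits.
#'
#' @param degrees Integer vector of 5 scale degrees.
#' @return Integer vector of 4 values in `{-1, 0, +1}`.
#' @examples
#' contour_transform(c(0, 4, 6, 7, 10)) # all ascending
#' contour_transform(c(6, 6, 6, 6, 6))  # monotone control
#' @export
contour_transform <- function(degrees) {
  if (length(degrees) != 5 || any(is.na(degrees))) {
    stop("a tone sequence is exactly 5 scale degrees", call. = FALSE)
  }
  as.integer(sign(diff(as.numeric(degrees))))
}

# Serialization helpers: signals travel in CSV as 5 space-separated integers.

#' Convert between signal strings and degree vectors
#'
#' Signals are serialized as 5 space-separated integers (e.g. `"0 4 6 7 10"`).
#'
#' @param signal Character vector of serialized signals.
#' @return `signal_to_degrees`: a list of integer vectors;
#'   `degrees_to_signal`: a character vector.
#' @export
signal_to_degrees <- function(signal) {
  lapply(strsplit(signal, " ", fixed = TRUE), function(x) as.integer(x))
}

#' @rdname signal_to_degrees
#' @param degrees An integer vector of 5 degrees, or a list of them.
#' @export
degrees_to_signal <- function(degrees) {
  if (!is.list(degrees)) degrees <- list(degrees)
  vapply(degrees, function(d) paste(as.integer(d), collapse = " "), character(1))
}
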