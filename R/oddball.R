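#' Standard and deviant sequences of the auditory oddball localizer
#'
#' The standard pattern is the five-tone sequence with degrees 0, 2, 3, 4, 6
#' above the register's lowest tone (440, 521, 567, 617, 730.6 Hz in the low
#' register). Deviants alter only the fourth tone:
#' * the contour deviant (C-deviant) flips the direction of the 3rd-to-4th
#'   interval while preserving its absolute size (surface structure violated,
#'   interval size kept);
#' * the interval deviant (I-deviant) keeps the direction but changes the
#'   interval size (the smallest degree change satisfying the constraint).
#' Tones 1-3 and 5 are unchanged.
#'
#' Sequences are transposed across 3 registers whose lowest tones sit at
#' degrees 0, 1 and 3 above k = 440 Hz (about 440, 478.8 and 567 Hz).
#'
#' @param register Register index 1-3, or a degree offset via
#'   `register_offsets`.
#' @param register_offsets Degree offsets of the registers' lowest tones.
#' @param scale A [bp_scale_config()] (supplies k and the tritave division).
#' @return A list with integer degree vectors `standard`, `c_deviant`,
#'   `i_deviant` and the `register` offset used.
#' @export
oddball_sequences <- function(register = 1,
                              register_offsets = c(0L, 1L, 3L),
                              scale = bp_scale_config()) {
  if (!register %in% seq_along(register_offsets)) {
    stop("`register` must index into `register_offsets`", call. = FALSE)
  }
  off <- register_offsets[register]
  standard <- off + c(0L, 2L, 3L, 4L, 6L)
  # 3rd -> 4th interval of the standard is +1; flip it: 4th = 3rd - 1
  c_dev <- standard
  c_dev[4] <- standard[3] - 1L
  # same direction, different size: smallest change is interval +2
  i_dev <- standard
  i_dev[4] <- standard[3] + 2L
  max_degree <- scale$steps_per_tritave
  for (s in list(standard, c_dev, i_dev)) {
    if (any(s < 0L) || any(s > max_degree)) {
      stop("register offset ", off, " pushes degrees out of range [0, ",
           max_degree, "]", call. = FALSE)
    }
  }
  list(standard = standard, c_deviant = c_dev, i_deviant = i_dev,
       register = off)
}

#' Generate an auditory oddball stimulus design
#'
#' Builds a stream of `n_total` trials with 80% standards and 10% each of
#' contour and interval deviants. Deviants of the same type always occur in
#' pairs presented in close temporal succession: the onset gap between pair
#' members falls in `pair_gap` (2400-4800 ms), i.e. 2-4 stimulus positions
#' at the 1200 ms onset-to-onset spacing (450 ms sequence + 750 ms ISI),
#' with only standards in between. Each trial's register is drawn uniformly
#' from the 3 transpositions.
#'
#' Pair blocks are placed uniformly at random among the standards (run
#' lengths between blocks follow the uniform-composition distribution); a
#' deterministic rebalancing step then lengthens the longest standard runs
#' until at least `n_total/10` standards are flankable by 5 standards on
#' each side, so that balanced event extraction is always feasible.
#'
#' @param n_total Total number of stimuli (default 1260; must be divisible
#'   by 20 so the 80/10/10 proportions and pairing are exact).
#' @param pair_gap Allowed onset gap between pair members, ms.
#' @param isi Intersequence interval, ms.
#' @param seq_duration_ms Duration of one sequence (5 x 50 ms tones + 4 x
#'   50 ms gaps = 450 ms).
#' @param flank Flanking standards required around an extractable standard.
#' @return An `oddball_design`: a tibble of trials (`index`, `condition`,
#'   `onset_ms`, `register`, `signal`) with attributes `n_total`, `isi`,
#'   `spacing_ms`.
#' @export
generate_design <- function(n_total = 1260, pair_gap = c(2400, 4800),
                            isi = 750, seq_duration_ms = 450, flank = 5) {
  n_total <- as.integer(n_total)
  if (n_total %% 20L != 0L) {
    stop("`n_total` must be divisible by 20 for exact 80/10/10 pairing",
         call. = FALSE)
  }
  n_dev_each <- n_total %/% 10L          # 126 at the default
  n_pairs_each <- n_dev_each %/% 2L      # 63 same-type pairs per deviant type
  n_std <- n_total - 2L * n_dev_each     # 1008
  spacing <- seq_duration_ms + isi       # 1200 ms onset-to-onset
  gaps_pos <- seq(ceiling(pair_gap[1] / spacing), floor(pair_gap[2] / spacing))
  if (length(gaps_pos) == 0) {
    stop("`pair_gap` window admits no whole stimulus positions", call. = FALSE)
  }

  n_pairs <- 2L * n_pairs_each
  pair_type <- sample(rep(c("C_DEV", "I_DEV"), c(n_pairs_each, n_pairs_each)))
  g <- sample(gaps_pos, n_pairs, replace = TRUE)   # positions between members
  internal <- g - 1L                               # standards inside each pair
  n_sep <- n_pairs + 1L
  free <- n_std - sum(internal)
  if (free < n_sep - 2L) {
    stop("infeasible: too many deviants for the pair-gap rule at n_total = ",
         n_total, call. = FALSE)
  }
  # Separator runs: uniform composition of `free` standards into n_sep parts,
  # interior parts >= 1 (pair blocks never touch), exterior parts >= 0.
  mins <- c(0L, rep(1L, n_sep - 2L), 0L)
  sep <- compose_uniform(free - sum(mins), n_sep) + mins

  # Rebalance: move standards from short runs into the longest runs until
  # enough standards have `flank` standards on both sides.
  need <- n_dev_each
  eligible_count <- function(runs) sum(pmax(0L, runs - 2L * flank))
  while (eligible_count(sep) < need) {
    i <- which.max(sep)
    donors <- which(sep >= 1L & sep <= 2L * flank &
                      (sep > mins) & seq_len(n_sep) != i)
    if (length(donors) == 0) {
      stop("cannot rebalance standards to satisfy the flank rule",
           call. = FALSE)
    }
    j <- donors[which.min(sep[donors])]
    sep[j] <- sep[j] - 1L
    sep[i] <- sep[i] + 1L
  }

  cond <- character(0)
  pair_id <- integer(0)
  for (p in seq_len(n_pairs)) {
    cond <- c(cond, rep("STD", sep[p]),
              pair_type[p], rep("STD", internal[p]), pair_type[p])
    pair_id <- c(pair_id, rep(NA_integer_, sep[p]),
                 p, rep(NA_integer_, internal[p]), p)
  }
  cond <- c(cond, rep("STD", sep[n_sep]))
  pair_id <- c(pair_id, rep(NA_integer_, sep[n_sep]))
  stopifnot(length(cond) == n_total)

  reg <- sample.int(3L, n_total, replace = TRUE)
  seqs <- lapply(1:3, oddball_sequences)
  degree_of <- function(condition, register) {
    s <- seqs[[register]]
    switch(condition, STD = s$standard, C_DEV = s$c_deviant,
           I_DEV = s$i_deviant)
  }
  signal <- vapply(seq_len(n_total),
                   function(i) degrees_to_signal(degree_of(cond[i], reg[i])),
                   character(1))
  trials <- tibble::tibble(
    index = seq_len(n_total),
    condition = cond,
    pair_id = pair_id,
    onset_ms = (seq_len(n_total) - 1L) * spacing,
    register = reg,
    signal = signal
  )
  structure(trials, class = c("oddball_design", class(trials)),
            n_total = n_total, isi = isi, spacing_ms = spacing, flank = flank)
}

# Uniform composition of N into k non-negative parts (stars and bars).
compose_uniform <- function(N, k) {
  if (k == 1L) return(N)
  bars <- sort(sample.int(N + k - 1L, k - 1L))
  as.integer(diff(c(0L, bars, N + k)) - 1L)
}

#' Extract a balanced set of standard events
#'
#' Randomly selects, from the standards of a design, a subset equal in size
#' to one deviant category (126 in the default 1260-trial design), under the
#' constraint that each selected standard is preceded and followed by at
#' least `flank` other standards in the stimulus stream. The selected
#' standards are modeled implicitly in the localizer GLM so that the
#' explicit standard regressor is balanced against the deviants; the
#' remaining standards (882 by default) are modeled explicitly.
#'
#' @param design An [generate_design()] result.
#' @param n_modeled Number of standards to extract (default: one deviant
#'   category's count).
#' @param flank Required flanking standards on each side.
#' @return List with integer index vectors `modeled` and `remaining`.
#' @export
extract_balanced_standards <- function(design, n_modeled = NULL, flank = 5) {
  is_std <- design$condition == "STD"
  n <- nrow(design)
  if (is.null(n_modeled)) n_modeled <- sum(design$condition == "C_DEV")
  ok <- vapply(which(is_std), function(i) {
    lo <- i - flank; hi <- i + flank
    lo >= 1 && hi <= n && all(is_std[lo:hi])
  }, logical(1))
  eligible <- which(is_std)[ok]
  if (length(eligible) < n_modeled) {
    stop("only ", length(eligible), " standards satisfy the ", flank,
         "-standard flank rule; ", n_modeled, " needed", call. = FALSE)
  }
  modeled <- sort(sample(eligible, n_modeled))
  remaining <- setdiff(which(is_std), modeled)
  list(modeled = modeled, remaining = remaining)
}

#' Write / read a BIDS-style events table
#'
#' Columns: `onset` (s), `duration` (s), `trial_type`, `register`. A
#' write-then-read round trip reproduces the design's event timing.
#'
#' @param design An [generate_design()] result.
#' @param path Output TSV path.
#' @param seq_duration_ms Event duration in ms.
#' @return `write_events_table`: the path, invisibly. `read_events_table`:
#'   a tibble.
#' @export
write_events_table <- function(design, path, seq_duration_ms = 450) {
  ev <- tibble::tibble(
    onset = design$onset_ms / 1000,
    duration = seq_duration_ms / 1000,
    trial_type = design$condition,
    register = design$register
  )
  readr::write_tsv(ev, path)
  invisible(path)
}

#' @rdname write_events_table
#' @export
read_events_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    onset = readr::col_double(), duration = readr::col_double(),
    trial_type = readr::col_character(), register = readr::col_integer()
  ))
}

#' Synthesize the waveform of one oddball sequence
#'
#' Five 50 ms sinusoidal tones with 5 ms linear rise and fall, separated by
#' 50 ms of silence (450 ms per sequence). Returns the raw waveform; no
#' audio container is written.
#'
#' @param degrees Integer vector of 5 scale degrees.
#' @param sample_rate Samples per second (>= 8000).
#' @param scale A [bp_scale_config()].
#' @return Numeric waveform in `[-1, 1]` with attribute `sample_rate`.
#' @export
render_sequence_audio <- function(degrees, sample_rate = 44100,
                                  scale = bp_scale_config()) {
  if (sample_rate < 8000) stop("`sample_rate` must be >= 8 kHz", call. = FALSE)
  freqs <- sequence_frequencies(degrees, scale, game_mode = FALSE)
  tone_n <- round(0.050 * sample_rate)
  gap_n <- round(0.050 * sample_rate)
  ramp_n <- round(0.005 * sample_rate)
  env <- rep(1, tone_n)
  env[seq_len(ramp_n)] <- seq(0, 1, length.out = ramp_n)
  env[tone_n - seq_len(ramp_n) + 1] <- seq(0, 1, length.out = ramp_n)
  t <- seq_len(tone_n) / sample_rate
  wave <- numeric(0)
  for (i in seq_along(freqs)) {
    tone <- env * sin(2 * pi * freqs[i] * t)
    wave <- c(wave, tone, if (i < length(freqs)) numeric(gap_n))
  }
  structure(wave, sample_rate = sample_rate)
}

#' Synthesize the waveform of (part of) an oddball run
#'
#' Concatenates per-trial sequence waveforms separated by the 750 ms ISI.
#'
#' @param design An [generate_design()] result.
#' @param sample_rate Samples per second.
#' @param trials Trial indices to render (default: first 10; a full
#'   1260-trial run is ~25 min of audio).
#' @return Numeric waveform with attribute `sample_rate`.
#' @export
render_audio <- function(design, sample_rate = 44100,
                         trials = seq_len(min(10, nrow(design)))) {
  isi_n <- round(attr(design, "isi") / 1000 * sample_rate)
  parts <- lapply(trials, function(i) {
    d <- signal_to_degrees(design$signal[i])[[1]]
    c(as.numeric(render_sequence_audio(d, sample_rate)), numeric(isi_n))
  })
  structure(unlist(parts), sample_rate = sample_rate)
}
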