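#' The five emotion states of the signaling games
#'
#' Three simple emotions and two compound ones; senders see one per trial as
#' a facial expression and signal it with a five-tone sequence.
#'
#' @return Character vector of the 5 emotion labels.
#' @export
emotions <- function() {
  c("peace", "joy", "sadness", "peace_joy", "peace_sadness")
}

#' Analysis configuration
#'
#' Collects the measure options shared across the pipeline, with defaults
#' matching the study design: a 70-trial learning game and a 30-trial
#' transmission game, the strict upper half of Game 1 (trials 36-70) as the
#' "second half", 100 Monte-Carlo shuffles for the interval compression
#' ratio, and a Bonferroni family of 7 tests at family alpha 0.05.
#'
#' @param n_trials_g1,n_trials_g2 Trials per game.
#' @param second_half Trial indices forming the second half of Game 1.
#' @param coordination_method `"set_mean"` (mean similarity to every signal
#'   the receiver mapped to the emotion) or `"modal"` (similarity to the
#'   receiver's modal signal only).
#' @param transmission_method `"modal"` or `"all_trials"`.
#' @param icr_shuffles Monte-Carlo shuffles for [icr()].
#' @param icr_exact Use exhaustive permutation enumeration in [icr()].
#' @param family_alpha,n_tests Bonferroni family for [correlate_behavior()].
#' @return A named list of class `tonetrans_config`.
#' @export
run_config <- function(n_trials_g1 = 70L, n_trials_g2 = 30L,
                       second_half = 36:70,
                       coordination_method = c("set_mean", "modal"),
                       transmission_method = c("modal", "all_trials"),
                       icr_shuffles = 100L, icr_exact = FALSE,
                       family_alpha = 0.05, n_tests = 7L) {
  structure(list(
    n_trials_g1 = as.integer(n_trials_g1),
    n_trials_g2 = as.integer(n_trials_g2),
    second_half = as.integer(second_half),
    coordination_method = match.arg(coordination_method),
    transmission_method = match.arg(transmission_method),
    icr_shuffles = as.integer(icr_shuffles),
    icr_exact = isTRUE(icr_exact),
    family_alpha = family_alpha,
    n_tests = as.integer(n_tests)
  ), class = "tonetrans_config")
}

#' Hamming similarity between two equal-length symbol sequences
#'
#' The Hamming distance is the number of pointwise substitutions S needed to
#' make two strings of equal length L identical, normalized to S/L in
#' `[0, 1]`; similarity is `1 - S/L`. Tone mode compares the 5 degrees,
#' contour mode the 4 interval directions.
#'
#' @param a,b Vectors of symbols of equal length.
#' @return Similarity in `[0, 1]`.
#' @examples
#' hamming_similarity(c(0, 4, 6, 7, 10), c(0, 4, 6, 7, 4)) # 0.8
#' @export
hamming_similarity <- function(a, b) {
  if (length(a) != length(b) || length(a) == 0) {
    stop("sequences must be non-empty and of equal length", call. = FALSE)
  }
  mean(a == b)
}

#' @rdname hamming_similarity
#' @export
hamming_distance <- function(a, b) 1 - hamming_similarity(a, b)

# Symbol representation used by a distance mode: the 5 degrees (tone) or the
# 4 interval directions (contour).
signal_symbols <- function(signal, distance_mode) {
  d <- signal_to_degrees(signal)[[1]]
  if (distance_mode == "contour") contour_transform(d) else d
}

# Deterministic ordering key for tie-breaking among signals.
signal_sort_key <- function(signal) {
  vapply(signal_to_degrees(signal),
         function(d) paste(sprintf("%04d", d + 100L), collapse = " "),
         character(1))
}

#' Modal signaling code of a player
#'
#' Tallies, per emotion, the signals a player paired with that emotion: for
#' `role = "sender"`, the signal produced for each shown state; for
#' `role = "receiver"`, the heard signal for each guessed emotion. The modal
#' signal is the most frequent one. Ties are broken deterministically: among
#' tied signals the one whose maximal count was attained at the earliest
#' trial wins, then the lowest lexicographic degree sequence.
#'
#' @param log A game-log tibble (see [read_game_logs()] for the schema).
#' @param role `"sender"` or `"receiver"`.
#' @param window Optional trial indices to restrict the tally (e.g. the
#'   second half of Game 1); `NULL` uses all trials.
#' @return A tibble with one row per emotion: `emotion`, `signal` (modal,
#'   `NA` when no trial contributed), `count`, `n_contributing`, `flagged`.
#'   Emotions with no contributing trials are flagged missing and a warning
#'   is raised.
#' @export
modal_code <- function(log, role = c("sender", "receiver"), window = NULL) {
  role <- match.arg(role)
  if (!is.null(window)) {
    if (length(window) == 0) stop("`window` must be non-empty", call. = FALSE)
    log <- log[log$trial %in% window, , drop = FALSE]
  }
  key <- if (role == "sender") log$state else log$guess
  all_sigs <- log$signal
  all_trials <- log$trial
  ems <- emotions()
  sig_out <- rep(NA_character_, 5L)
  count_out <- integer(5L)
  n_out <- integer(5L)
  for (k in seq_along(ems)) {
    rows <- which(key == ems[k])
    n_out[k] <- length(rows)
    if (length(rows) == 0) next
    sigs <- all_sigs[rows]
    counts <- table(sigs)
    m <- max(counts)
    top <- names(counts)[counts == m]
    if (length(top) > 1) {
      # trial index at which each tied signal first reached the max count
      attain <- vapply(top, function(s) all_trials[rows[sigs == s][m]],
                       numeric(1))
      top <- top[attain == min(attain)]
      if (length(top) > 1) top <- top[order(signal_sort_key(top))][1]
    }
    sig_out[k] <- top
    count_out[k] <- as.integer(m)
  }
  out <- tibble::tibble(emotion = ems, signal = sig_out, count = count_out,
                        n_contributing = n_out, flagged = n_out == 0L)
  if (any(out$flagged)) {
    warning("no contributing trials for emotion(s): ",
            paste(out$emotion[out$flagged], collapse = ", "), call. = FALSE)
  }
  out
}

# Mean of per-emotion values over non-missing emotions, warning on exclusion.
mean_over_emotions <- function(values, what) {
  miss <- is.na(values)
  if (all(miss)) {
    warning("all emotions missing for ", what, call. = FALSE)
    return(NA_real_)
  }
  if (any(miss)) {
    warning("excluding emotion(s) with no data from ", what, ": ",
            paste(names(values)[miss], collapse = ", "), call. = FALSE)
  }
  mean(values[!miss])
}

#' Coordination index of a learning game
#'
#' Measures how far the receiver's end-of-game mappings agree with the
#' sender's code: for each emotion, the similarity between the sender's
#' signal and the signals the receiver mapped to that emotion over the
#' second half of the game, averaged over the five emotions. 1 means a
#' fully shared signaling system, 0 a disjoint one.
#'
#' @param log_g1 Game-1 log (sender plays a constant code).
#' @param distance_mode `"tone"` (5 degrees) or `"contour"` (4 directions).
#' @param method `"set_mean"`: mean similarity to every signal the receiver
#'   mapped to the emotion in the window; `"modal"`: similarity to the
#'   receiver's modal signal only.
#' @param window Trial indices forming the second half (default 36-70).
#' @return List with `per_emotion` (named numeric) and `mean`.
#' @export
coordination <- function(log_g1, distance_mode = c("tone", "contour"),
                         method = c("set_mean", "modal"),
                         window = 36:70) {
  distance_mode <- match.arg(distance_mode)
  method <- match.arg(method)
  sender <- modal_code(log_g1, "sender")
  half <- log_g1[log_g1$trial %in% window, , drop = FALSE]
  per <- vapply(emotions(), function(e) {
    s_sig <- sender$signal[sender$emotion == e]
    if (is.na(s_sig)) return(NA_real_)
    s_sym <- signal_symbols(s_sig, distance_mode)
    if (method == "set_mean") {
      heard <- half$signal[half$guess == e]
      if (length(heard) == 0) return(NA_real_)
      degs <- signal_to_degrees(heard)
      syms <- if (distance_mode == "contour") lapply(degs, contour_transform)
              else degs
      mean(vapply(syms, function(x) mean(x == s_sym), numeric(1)))
    } else {
      rc <- suppressWarnings(modal_code(half, "receiver"))
      r_sig <- rc$signal[rc$emotion == e]
      if (is.na(r_sig)) return(NA_real_)
      hamming_similarity(s_sym, signal_symbols(r_sig, distance_mode))
    }
  }, numeric(1))
  list(per_emotion = per, mean = mean_over_emotions(per, "coordination"))
}

#' Transmission fidelity between adjacent games
#'
#' Similarity between the signals mapped to the same emotion by the senders
#' of adjacent games: the seeding code delivered in Game 1 versus the code
#' the participant reproduces as sender in Game 2. 1 means faithful
#' transmission, 0 an entirely new code.
#'
#' @param seed_code Code tibble (as from [modal_code()] or
#'   [make_seed_codes()]): columns `emotion`, `signal`.
#' @param log_g2 Game-2 log with the participant as sender.
#' @param distance_mode `"tone"` or `"contour"`.
#' @param method `"modal"`: compare against the Game-2 sender's modal signal
#'   per emotion; `"all_trials"`: average similarity over every Game-2 trial.
#' @return List with `per_emotion` and `mean` in `[0, 1]`.
#' @export
transmission <- function(seed_code, log_g2,
                         distance_mode = c("tone", "contour"),
                         method = c("modal", "all_trials")) {
  distance_mode <- match.arg(distance_mode)
  method <- match.arg(method)
  per <- if (method == "modal") {
    g2 <- modal_code(log_g2, "sender")
    code_similarity(seed_code, g2, distance_mode)
  } else {
    vapply(emotions(), function(e) {
      s_sig <- seed_code$signal[seed_code$emotion == e]
      played <- log_g2$signal[log_g2$state == e]
      if (is.na(s_sig) || length(played) == 0) return(NA_real_)
      s_sym <- signal_symbols(s_sig, distance_mode)
      mean(vapply(played, function(x)
        hamming_similarity(s_sym, signal_symbols(x, distance_mode)),
        numeric(1)))
    }, numeric(1))
  }
  list(per_emotion = per, mean = mean_over_emotions(per, "transmission"))
}

# Per-emotion Hamming similarity between two codes.
code_similarity <- function(code_a, code_b, distance_mode) {
  vapply(emotions(), function(e) {
    a <- code_a$signal[code_a$emotion == e]
    b <- code_b$signal[code_b$emotion == e]
    if (length(a) != 1 || length(b) != 1 || is.na(a) || is.na(b)) {
      return(NA_real_)
    }
    hamming_similarity(signal_symbols(a, distance_mode),
                       signal_symbols(b, distance_mode))
  }, numeric(1))
}

#' Innovation introduced by a participant between games
#'
#' Within-player mean Hamming distance between the code the participant
#' learned as receiver (modal signal per emotion over the second half of
#' Game 1) and the code they reproduced as sender in Game 2 (modal signal
#' per emotion). 0 means no change; values near 1 indicate a reorganized
#' signaling system.
#'
#' @inheritParams coordination
#' @param log_g2 Game-2 log of the same participant as sender.
#' @return List with `per_emotion` distances and `mean` in `[0, 1]`.
#' @export
innovation <- function(log_g1, log_g2, distance_mode = c("tone", "contour"),
                       window = 36:70) {
  distance_mode <- match.arg(distance_mode)
  learned <- modal_code(log_g1, "receiver", window = window)
  produced <- modal_code(log_g2, "sender")
  per <- 1 - code_similarity(learned, produced, distance_mode)
  list(per_emotion = per, mean = mean_over_emotions(per, "innovation"))
}

#' Asymmetry of information flow in a game
#'
#' `A = (S - R) / (S + R)` where S counts code changes by the sender and R
#' by the receiver. A sender change is a trial whose produced signal for a
#' state differs from that sender's most recent signal for the same state; a
#' receiver change is a trial whose guess for a previously heard signal
#' differs from the most recent guess for the identical signal. First
#' occurrences are not changes. A ranges from -1 (only the receiver adapts,
#' as in Game 1 where the confederate's code is fixed by design) to +1.
#'
#' @param log A game log.
#' @return Value in `[-1, 1]`, or `NA` (with a warning) when no changes
#'   occurred at all.
#' @export
asymmetry <- function(log) {
  s_changes <- 0L
  r_changes <- 0L
  last_signal <- list()  # state -> last signal produced by sender
  last_guess <- list()   # signal -> last guess by receiver
  for (i in seq_len(nrow(log))) {
    st <- log$state[i]; sig <- log$signal[i]; g <- log$guess[i]
    if (!is.null(last_signal[[st]]) && last_signal[[st]] != sig) {
      s_changes <- s_changes + 1L
    }
    last_signal[[st]] <- sig
    if (!is.null(last_guess[[sig]]) && last_guess[[sig]] != g) {
      r_changes <- r_changes + 1L
    }
    last_guess[[sig]] <- g
  }
  if (s_changes + r_changes == 0L) {
    warning("no code changes by either player; asymmetry undefined",
            call. = FALSE)
    return(NA_real_)
  }
  (s_changes - r_changes) / (s_changes + r_changes)
}

#' Accuracy: number of correct trials
#'
#' @param log_g1 A game log (Game 1 by convention).
#' @return Integer count of trials where the receiver's guess matched the
#'   sender's state.
#' @export
accuracy <- function(log_g1) {
  sum(log_g1$state == log_g1$guess)
}

#' Shannon entropy of a symbol sequence
#'
#' `H(X) = -sum p(x_i) log2 p(x_i)` with `p` the empirical relative
#' frequency of each symbol within the sequence; `0 * log 0` is 0.
#'
#' @param symbols Non-empty vector over a finite alphabet.
#' @return Entropy in bits; 0 for a constant sequence, at most
#'   `log2(number of distinct symbols)`.
#' @examples
#' shannon_entropy(c(1, 1, -1, -1))  # 1 bit
#' shannon_entropy(c(1, 1, 1, -1))   # 0.811 bits
#' @export
shannon_entropy <- function(symbols) {
  if (length(symbols) == 0) stop("empty symbol sequence", call. = FALSE)
  p <- as.numeric(table(symbols)) / length(symbols)
  -sum(p * log2(p))
}

#' Entropy of a signal in tone or contour mode
#'
#' @param signal Serialized signal (or 5-degree integer vector).
#' @param distance_mode `"tone"`: entropy over the 5 degrees; `"contour"`:
#'   over the 4 interval directions.
#' @return Entropy in bits.
#' @export
sequence_entropy <- function(signal, distance_mode = c("tone", "contour")) {
  distance_mode <- match.arg(distance_mode)
  d <- if (is.character(signal)) signal_to_degrees(signal)[[1]] else signal
  if (distance_mode == "contour") shannon_entropy(contour_transform(d))
  else shannon_entropy(d)
}

#' Mean entropy of a signaling code
#'
#' Mean per-signal Shannon entropy across the five emotions, computed
#' separately on tone sequences and on their contour transforms.
#'
#' @param signals Character vector of signals (one per emotion) or a code
#'   tibble with a `signal` column.
#' @param distance_mode `"tone"` or `"contour"`.
#' @return Mean entropy in bits (missing signals excluded with a warning).
#' @export
mean_code_entropy <- function(signals, distance_mode = c("tone", "contour")) {
  distance_mode <- match.arg(distance_mode)
  if (is.data.frame(signals)) signals <- signals$signal
  h <- vapply(signals, function(s) {
    if (is.na(s)) NA_real_ else sequence_entropy(s, distance_mode)
  }, numeric(1))
  mean_over_emotions(h, "mean code entropy")
}

#' Regularization delta between games
#'
#' Entropy kind: `H_g1 - H_g2`, positive when the participant made the
#' code less entropic (regularization). ICR kind: `ICR_g2 - ICR_g1`,
#' positive when intervals were compressed toward proximity.
#'
#' @param measure_g1,measure_g2 The per-game values.
#' @param kind `"entropy"` or `"icr"`.
#' @return Signed delta; `NA` inputs propagate.
#' @export
regularization_delta <- function(measure_g1, measure_g2,
                                 kind = c("entropy", "icr")) {
  kind <- match.arg(kind)
  if (kind == "entropy") measure_g1 - measure_g2
  else measure_g2 - measure_g1
}
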