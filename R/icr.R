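#' Interval compression ratio (ICR) of a tone sequence
#'
#' Pitch proximity bias of a melody, measured against its own shuffles: the
#' numerator is the mean, over random reorderings of the tones, of the
#' shuffled sequence's mean absolute successive interval (in scale-degree
#' units, i.e. macrotones); the denominator is the mean absolute successive
#' interval of the original sequence. Values above 1 indicate a bias towards
#' small (proximal) intervals.
#'
#' The Monte-Carlo estimator samples `n_shuffles` position permutations
#' uniformly with replacement from the caller's RNG stream; `exact = TRUE`
#' enumerates all 120 position permutations of the 5 tones instead and is
#' deterministic.
#'
#' A constant sequence has a zero denominator; by convention its ICR is 1.0
#' and the result carries attribute `degenerate = TRUE`.
#'
#' @param degrees Serialized signal or integer vector of 5 scale degrees.
#' @param n_shuffles Number of Monte-Carlo shuffles (study default 100).
#' @param exact Enumerate all position permutations instead of sampling.
#' @return The ratio (numeric scalar) with attribute `degenerate`.
#' @examples
#' set.seed(1)
#' icr(c(0, 4, 6, 7, 10))               # Monte-Carlo, 100 shuffles
#' icr(c(0, 4, 6, 7, 10), exact = TRUE) # exhaustive
#' @export
icr <- function(degrees, n_shuffles = 100, exact = FALSE) {
  if (is.character(degrees)) degrees <- signal_to_degrees(degrees)[[1]]
  if (length(degrees) != 5 || any(is.na(degrees))) {
    stop("a tone sequence is exactly 5 scale degrees", call. = FALSE)
  }
  degrees <- as.numeric(degrees)
  denom <- mean(abs(diff(degrees)))
  if (denom == 0) {
    return(structure(1.0, degenerate = TRUE))
  }
  num <- if (exact) {
    perms <- position_permutations(5L)
    mean(apply(perms, 1, function(p) mean(abs(diff(degrees[p])))))
  } else {
    mean(replicate(n_shuffles, mean(abs(diff(sample(degrees))))))
  }
  structure(num / denom, degenerate = FALSE)
}

# All permutations of 1..n as an n! x n matrix (recursive construction).
position_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- position_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

#' Mean ICR of a signaling code
#'
#' Mean interval compression ratio across the five emotions' signals. The
#' monotone control signal is degenerate (constant pitch); its ICR is 1.0 by
#' convention, so both the mean including degenerate signals and the mean
#' excluding them are returned.
#'
#' @param signals Character vector of signals or code tibble.
#' @inheritParams icr
#' @return List with `incl` (degenerates counted as 1.0), `excl`
#'   (degenerates dropped), and `per_emotion` values.
#' @export
mean_code_icr <- function(signals, n_shuffles = 100, exact = FALSE) {
  if (is.data.frame(signals)) signals <- signals$signal
  vals <- lapply(signals, function(s) {
    if (is.na(s)) return(structure(NA_real_, degenerate = NA))
    icr(s, n_shuffles = n_shuffles, exact = exact)
  })
  per <- vapply(vals, as.numeric, numeric(1))
  names(per) <- if (length(per) == length(emotions())) emotions() else NULL
  degen <- vapply(vals, function(v) isTRUE(attr(v, "degenerate")), logical(1))
  excl <- per[!degen & !is.na(per)]
  list(
    incl = mean_over_emotions(per, "mean code ICR"),
    excl = if (length(excl)) mean(excl) else NA_real_,
    per_emotion = per
  )
}

#' All behavioral and structural measures for one participant
#'
#' Drives every game measure over a participant's pair of logs: the
#' Hamming-based learning indices (coordination, transmission, innovation),
#' asymmetry and accuracy, mean tone/contour entropies and mean ICRs per
#' game, and the regularization deltas between games. Game-1 entropies and
#' ICRs are computed on the seeding code's signals (the system delivered by
#' the confederate sender); Game-2 values on the participant-as-sender modal
#' signals.
#'
#' @param log_g1,log_g2 The participant's Game-1 and Game-2 logs.
#' @param seed_code The seeding code tibble delivered in Game 1.
#' @param config A [run_config()].
#' @return One-row tibble of measures.
#' @export
compute_measure_set <- function(log_g1, log_g2, seed_code,
                                config = run_config()) {
  half <- config$second_half
  g2_code <- modal_code(log_g2, "sender")

  coord_t <- coordination(log_g1, "tone", config$coordination_method, half)
  coord_c <- coordination(log_g1, "contour", config$coordination_method, half)
  trans_t <- transmission(seed_code, log_g2, "tone", config$transmission_method)
  trans_c <- transmission(seed_code, log_g2, "contour",
                          config$transmission_method)
  innov_t <- innovation(log_g1, log_g2, "tone", half)
  innov_c <- innovation(log_g1, log_g2, "contour", half)

  h_t_g1 <- mean_code_entropy(seed_code, "tone")
  h_c_g1 <- mean_code_entropy(seed_code, "contour")
  h_t_g2 <- mean_code_entropy(g2_code, "tone")
  h_c_g2 <- mean_code_entropy(g2_code, "contour")
  icr1 <- mean_code_icr(seed_code, config$icr_shuffles, config$icr_exact)
  icr2 <- mean_code_icr(g2_code, config$icr_shuffles, config$icr_exact)

  tibble::tibble(
    participant_id = log_g1$participant_id[1],
    coordination_tone = coord_t$mean,
    coordination_contour = coord_c$mean,
    transmission_tone = trans_t$mean,
    transmission_contour = trans_c$mean,
    innovation_tone = innov_t$mean,
    innovation_contour = innov_c$mean,
    asymmetry_g2 = asymmetry(log_g2),
    accuracy = accuracy(log_g1),
    entropy_tone_g1 = h_t_g1,
    entropy_tone_g2 = h_t_g2,
    entropy_contour_g1 = h_c_g1,
    entropy_contour_g2 = h_c_g2,
    icr_g1 = icr1$incl,
    icr_g2 = icr2$incl,
    icr_g1_excl = icr1$excl,
    icr_g2_excl = icr2$excl,
    delta_entropy_tone = regularization_delta(h_t_g1, h_t_g2, "entropy"),
    delta_entropy_contour = regularization_delta(h_c_g1, h_c_g2, "entropy"),
    delta_icr = regularization_delta(icr1$incl, icr2$incl, "icr")
  )
}
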