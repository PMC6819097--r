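#' The two counterbalanced seed code sets
#'
#' Each seeding set maps the five emotions to five-tone signals built from
#' the game degrees `{0, 4, 6, 7, 10}` whose contour entropies follow the
#' study profile: two high-entropy signals (H = 1 bit, a 2/2 split of ups
#' and downs), two low-entropy signals (H = 0.811 bits, a 3/1 split), and
#' one monotone control (H = 0 bits, constant pitch). The two sets share
#' the entropy profile but differ in tone content; the starting material is
#' counterbalanced across participants.
#'
#' @param scale A [bp_scale_config()]; degrees are validated against its
#'   allowed set.
#' @return Named list of two code tibbles (`A`, `B`) with columns
#'   `emotion`, `signal`.
#' @export
make_seed_codes <- function(scale = bp_scale_config()) {
  sets <- list(
    A = list(
      c(0L, 4L, 7L, 4L, 0L),    # up-up-down-down: H = 1
      c(4L, 7L, 0L, 10L, 6L),   # up-down-up-down: H = 1
      c(0L, 4L, 6L, 10L, 7L),   # up-up-up-down:   H = 0.811
      c(7L, 0L, 4L, 6L, 10L),   # down-up-up-up:   H = 0.811
      c(6L, 6L, 6L, 6L, 6L)     # monotone control: H = 0
    ),
    B = list(
      c(4L, 6L, 10L, 6L, 4L),   # up-up-down-down: H = 1
      c(0L, 10L, 4L, 7L, 0L),   # up-down-up-down: H = 1
      c(4L, 0L, 6L, 7L, 10L),   # down-up-up-up:   H = 0.811
      c(10L, 7L, 6L, 4L, 6L),   # down-down-down-up: H = 0.811
      c(0L, 0L, 0L, 0L, 0L)     # monotone control: H = 0
    )
  )
  lapply(sets, function(set) {
    for (d in set) validate_tone_sequence(d, scale)
    tibble::tibble(emotion = emotions(), signal = degrees_to_signal(set))
  })
}

#' Participant parameters of the generative agent model
#'
#' The agent model is a deliberately minimal mechanism producing the sign
#' structure the analysis tests. `ability` is a latent standard-normal
#' scalar; the receiver's per-trial probability of a correct guess in Game 1
#' is `plogis(intercept + learn_rate * exposures(e) * exp(ability))`, where
#' `exposures(e)` counts presentations of the state up to and including the
#' current trial (so learning acts from the first hearing, and the
#' infinite-ability limit is a perfect game). In Game 2 the
#' participant reproduces the learned code after a one-time mutation:
#' each position of each signal is altered independently with probability
#' `innovation_rate`; an altered position copies its left neighbour's degree
#' with probability `regularization_bias` (a contour-smoothing,
#' interval-shrinking move), else takes a uniform random allowed degree.
#'
#' @param ability Latent ability (standard-normal scale).
#' @param learn_rate Per-exposure log-odds increment (>= 0).
#' @param innovation_rate Probability a position is altered in Game 2.
#' @param regularization_bias Probability an altered position copies left.
#' @param intercept Baseline log-odds of a correct guess (default: chance,
#'   `qlogis(0.2)` for 5 emotions).
#' @return A `participant_params` list.
#' @export
participant_params <- function(ability = 0, learn_rate = 0.15,
                               innovation_rate = 0.25,
                               regularization_bias = 0.3,
                               intercept = stats::qlogis(0.2)) {
  stopifnot(learn_rate >= 0,
            innovation_rate >= 0, innovation_rate <= 1,
            regularization_bias >= 0, regularization_bias <= 1)
  structure(list(ability = ability, learn_rate = learn_rate,
                 innovation_rate = innovation_rate,
                 regularization_bias = regularization_bias,
                 intercept = intercept),
            class = "participant_params")
}

# Balanced state schedule: emotions cycled in random order per 5-trial block.
state_schedule <- function(n_trials) {
  blocks <- ceiling(n_trials / 5L)
  s <- unlist(lapply(seq_len(blocks), function(b) sample(emotions())))
  s[seq_len(n_trials)]
}

#' Simulate Game 1 (learning game)
#'
#' The confederate sender plays the seeding code verbatim on every trial
#' (the confederate is instructed to keep the mapping fixed throughout
#' Game 1, which makes the game's asymmetry -1 by design whenever the
#' receiver revises at least once). States are balanced: each emotion
#' appears once per 5-trial block, order randomized within block. The
#' receiver guesses correctly with the logistic learning probability, else
#' uniformly among the four wrong emotions.
#'
#' @param params A [participant_params()].
#' @param seed_code A seed code tibble (`emotion`, `signal`).
#' @param participant_id Identifier stored in the log.
#' @param n_trials Number of trials (study default 70).
#' @return A game-log tibble (see [read_game_logs()] for the schema).
#' @export
simulate_game1 <- function(params, seed_code, participant_id = "p1",
                           n_trials = 70L) {
  states <- state_schedule(n_trials)
  sig_of <- stats::setNames(seed_code$signal, seed_code$emotion)
  exposures <- stats::setNames(rep(0L, 5L), emotions())
  guess <- character(n_trials)
  for (i in seq_len(n_trials)) {
    e <- states[i]
    exposures[[e]] <- exposures[[e]] + 1L  # includes the current presentation
    p_correct <- stats::plogis(params$intercept +
      params$learn_rate * exposures[[e]] * exp(params$ability))
    guess[i] <- if (stats::runif(1) < p_correct) e
                else sample(setdiff(emotions(), e), 1L)
  }
  tibble::tibble(
    participant_id = participant_id,
    game_id = 1L,
    trial = seq_len(n_trials),
    sender_role = "confederate",
    state = states,
    signal = unname(sig_of[states]),
    guess = guess,
    correct = as.integer(states == guess)
  )
}

# One-time mutation of a learned code: positionwise innovation with a
# copy-left regularization move.
mutate_code <- function(learned_code, params, scale = bp_scale_config()) {
  signal <- vapply(learned_code$signal, function(s) {
    if (is.na(s)) return(NA_character_)
    d <- signal_to_degrees(s)[[1]]
    for (pos in seq_along(d)) {
      if (stats::runif(1) < params$innovation_rate) {
        if (pos > 1L && stats::runif(1) < params$regularization_bias) {
          d[pos] <- d[pos - 1L]
        } else {
          d[pos] <- sample(scale$allowed_degrees, 1L)
        }
      }
    }
    degrees_to_signal(d)
  }, character(1), USE.NAMES = FALSE)
  tibble::tibble(emotion = learned_code$emotion, signal = signal)
}

#' Simulate Game 2 (transmission game)
#'
#' The participant, now sender, transmits the code learned as receiver in
#' Game 1 after a one-time positionwise mutation (see
#' [participant_params()]), then plays the resulting code consistently for
#' all trials. The confederate receiver guesses correctly with fixed
#' probability `receiver_p_correct`, else uniformly among wrong emotions.
#'
#' @param params A [participant_params()].
#' @param learned_code The code the participant learned in Game 1 (modal
#'   signal per emotion from the second half, as receiver).
#' @param participant_id Identifier stored in the log.
#' @param n_trials Number of trials (study default 30).
#' @param receiver_p_correct Confederate receiver's accuracy.
#' @param scale A [bp_scale_config()] for the mutation move.
#' @return A game-log tibble.
#' @export
simulate_game2 <- function(params, learned_code, participant_id = "p1",
                           n_trials = 30L, receiver_p_correct = 0.5,
                           scale = bp_scale_config()) {
  code <- mutate_code(learned_code, params, scale)
  # fall back to a random signal for emotions never learned
  for (i in which(is.na(code$signal))) {
    code$signal[i] <- degrees_to_signal(sample(scale$allowed_degrees, 5L,
                                               replace = TRUE))
  }
  states <- state_schedule(n_trials)
  sig_of <- stats::setNames(code$signal, code$emotion)
  guess <- vapply(states, function(e) {
    if (stats::runif(1) < receiver_p_correct) e
    else sample(setdiff(emotions(), e), 1L)
  }, character(1), USE.NAMES = FALSE)
  tibble::tibble(
    participant_id = participant_id,
    game_id = 2L,
    trial = seq_len(n_trials),
    sender_role = "participant",
    state = states,
    signal = unname(sig_of[states]),
    guess = guess,
    correct = as.integer(states == guess)
  )
}

#' Cohort specification
#'
#' Study-scale defaults: 51 participants, 70/30 trials, seeding sets A/B
#' counterbalanced, six ROI-pair Fisher-z values per participant with the
#' lSTG-rSTG pair loading positively on ability (the sign pattern the
#' neurobehavioral stage tests), and a digit-span covariate.
#'
#' @param n_participants Cohort size.
#' @param n_trials_g1,n_trials_g2 Trials per game.
#' @param fc_means Baseline Fisher-z per ROI pair (named, 6 pairs).
#' @param fc_loadings Coefficient linking ability to each pair's z.
#' @param fc_noise_sd Residual SD of the z values (> 0).
#' @param digit_span_mean,digit_span_sd Digit-span score model.
#' @param learn_rate,regularization_bias Agent-model constants.
#' @param innovation_intercept,innovation_slope Innovation rate is
#'   `plogis(innovation_intercept - innovation_slope * ability)`: abler
#'   participants innovate less, mirroring the negative
#'   innovation-connectivity correlations.
#' @param master_seed Seed from which all per-participant substreams derive.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_participants = 51L,
                        n_trials_g1 = 70L, n_trials_g2 = 30L,
                        fc_means = c("lHG-rHG" = 0.8, "lHG-lSTG" = 0.6,
                                     "lHG-rSTG" = 0.4, "rHG-lSTG" = 0.4,
                                     "rHG-rSTG" = 0.6, "lSTG-rSTG" = 0.7),
                        fc_loadings = c("lHG-rHG" = 0, "lHG-lSTG" = 0,
                                        "lHG-rSTG" = 0, "rHG-lSTG" = 0,
                                        "rHG-rSTG" = 0, "lSTG-rSTG" = 0.25),
                        fc_noise_sd = 0.5,
                        digit_span_mean = 6.5, digit_span_sd = 1.1,
                        learn_rate = 0.15, regularization_bias = 0.3,
                        innovation_intercept = stats::qlogis(0.25),
                        innovation_slope = 0.5,
                        master_seed = 1L) {
  stopifnot(n_participants >= 2, fc_noise_sd > 0,
            identical(names(fc_means), fc_pair_labels()),
            identical(names(fc_loadings), fc_pair_labels()))
  structure(as.list(environment()), class = "cohort_spec")
}

#' ROI pair labels of the connectivity profile
#'
#' The six unordered pairs of the four auditory seeds (left/right Heschl's
#' gyrus, left/right superior temporal gyrus).
#'
#' @return Character vector of 6 pair labels.
#' @export
fc_pair_labels <- function() {
  c("lHG-rHG", "lHG-lSTG", "lHG-rSTG", "rHG-lSTG", "rHG-rSTG", "lSTG-rSTG")
}

#' Simulate Fisher-z connectivity profiles from latent ability
#'
#' `z_pair = mean_pair + loading_pair * ability + Normal(0, noise_sd)`.
#' The population correlation between a pair's z and ability is
#' `loading / sqrt(loading^2 + noise_sd^2)`; [loading_for_r()] inverts this.
#'
#' @param abilities Numeric vector of latent abilities.
#' @param spec A [cohort_spec()] (supplies means, loadings, noise SD).
#' @return Tibble: `participant_id`, `pair`, `z`.
#' @export
simulate_fc <- function(abilities, spec = cohort_spec()) {
  n <- length(abilities)
  pairs <- fc_pair_labels()
  rows <- lapply(seq_len(n), function(i) {
    z <- spec$fc_means + spec$fc_loadings * abilities[i] +
      stats::rnorm(length(pairs), 0, spec$fc_noise_sd)
    tibble::tibble(participant_id = sprintf("p%02d", i), pair = pairs,
                   z = unname(z))
  })
  dplyr::bind_rows(rows)
}

#' Loading that yields a target population correlation with ability
#'
#' Inverts `r = beta / sqrt(beta^2 + sigma^2)` for the linear-Gaussian
#' connectivity model.
#'
#' @param r Target population Pearson correlation (|r| < 1).
#' @param noise_sd Residual SD sigma.
#' @return The loading beta.
#' @export
loading_for_r <- function(r, noise_sd) {
  stopifnot(abs(r) < 1)
  r * noise_sd / sqrt(1 - r^2)
}

#' Simulate a full cohort
#'
#' Draws per-participant abilities and agent parameters, simulates both
#' games against the counterbalanced seeding sets, generates connectivity
#' profiles and digit spans, and returns the full bundle. Everything is
#' deterministic under `spec$master_seed`: per-participant substream seeds
#' are drawn once from the master stream, so participants are independent
#' and reproducible.
#'
#' @param spec A [cohort_spec()].
#' @param config A [run_config()] (supplies the second-half window used to
#'   extract each participant's learned code).
#' @return List with `participants` (tibble: id, seed_set, ability,
#'   innovation_rate, digit_span), `logs` (one tibble of all game logs),
#'   `fc` (long tibble of z values), `seed_codes`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), config = run_config()) {
  set.seed(spec$master_seed)
  n <- spec$n_participants
  sub_seeds <- sample.int(.Machine$integer.max, n + 1L)
  seed_codes <- make_seed_codes()
  abilities <- stats::rnorm(n)
  digit_span <- round(stats::rnorm(n, spec$digit_span_mean,
                                   spec$digit_span_sd), 1)
  seed_set <- rep(c("A", "B"), length.out = n)

  logs <- vector("list", n)
  innov <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(sub_seeds[i])
    innov[i] <- stats::plogis(spec$innovation_intercept -
                                spec$innovation_slope * abilities[i])
    par_i <- participant_params(
      ability = abilities[i], learn_rate = spec$learn_rate,
      innovation_rate = innov[i],
      regularization_bias = spec$regularization_bias
    )
    id <- sprintf("p%02d", i)
    g1 <- simulate_game1(par_i, seed_codes[[seed_set[i]]], id,
                         spec$n_trials_g1)
    learned <- suppressWarnings(
      modal_code(g1, "receiver", window = config$second_half)
    )
    g2 <- simulate_game2(par_i, learned, id, spec$n_trials_g2)
    logs[[i]] <- dplyr::bind_rows(g1, g2)
  }
  set.seed(sub_seeds[n + 1L])
  fc <- simulate_fc(abilities, spec)

  list(
    participants = tibble::tibble(
      participant_id = sprintf("p%02d", seq_len(n)),
      seed_set = seed_set, ability = abilities,
      innovation_rate = innov, digit_span = digit_span
    ),
    logs = dplyr::bind_rows(logs),
    fc = fc,
    seed_codes = seed_codes
  )
}

#' Compute measure sets for every participant of a cohort
#'
#' @param cohort A [simulate_cohort()] bundle (or a compatible list with
#'   `logs`, `participants`, `seed_codes`).
#' @param config A [run_config()].
#' @return Tibble of one [compute_measure_set()] row per participant.
#' @export
cohort_measures <- function(cohort, config = run_config()) {
  ids <- cohort$participants$participant_id
  rows <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    lg <- cohort$logs[cohort$logs$participant_id == id, , drop = FALSE]
    g1 <- lg[lg$game_id == 1L, , drop = FALSE]
    g2 <- lg[lg$game_id == 2L, , drop = FALSE]
    seed <- cohort$seed_codes[[cohort$participants$seed_set[i]]]
    suppressWarnings(compute_measure_set(g1, g2, seed, config))
  })
  dplyr::bind_rows(rows)
}
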