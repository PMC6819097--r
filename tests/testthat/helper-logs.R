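# Builders for small constructed game logs used across tests.

make_log <- function(state, signal, guess, game_id = 1L, id = "p1",
                     sender_role = if (game_id == 1L) "confederate"
                                   else "participant") {
  tibble::tibble(
    participant_id = id,
    game_id = as.integer(game_id),
    trial = seq_along(state),
    sender_role = sender_role,
    state = state,
    signal = signal,
    guess = guess,
    correct = as.integer(state == guess)
  )
}

# A Game-1 log in which the confederate plays `code` verbatim and the
# receiver's guess is supplied by `guess_fun(state, trial)`.
scripted_game1 <- function(code, n_trials = 70,
                           guess_fun = function(state, trial) state) {
  states <- rep(emotions(), length.out = n_trials)
  sig_of <- stats::setNames(code$signal, code$emotion)
  guess <- vapply(seq_len(n_trials),
                  function(i) guess_fun(states[i], i), character(1))
  make_log(states, unname(sig_of[states]), guess)
}

# A Game-2 log in which the participant-as-sender plays `code` verbatim.
scripted_game2 <- function(code, n_trials = 30, receiver_correct = TRUE) {
  states <- rep(emotions(), length.out = n_trials)
  sig_of <- stats::setNames(code$signal, code$emotion)
  guess <- if (receiver_correct) states
           else vapply(states, function(e) sample(setdiff(emotions(), e), 1),
                       character(1))
  make_log(states, unname(sig_of[states]), guess, game_id = 2L)
}

# A fully random (unstructured) game log over the allowed degrees.
random_log <- function(n_trials = 70, game_id = 1L) {
  deg <- bp_scale_config()$allowed_degrees
  states <- sample(emotions(), n_trials, replace = TRUE)
  signal <- vapply(seq_len(n_trials), function(i) {
    degrees_to_signal(sample(deg, 5, replace = TRUE))
  }, character(1))
  guess <- sample(emotions(), n_trials, replace = TRUE)
  make_log(states, signal, guess, game_id = game_id)
}

# Apply a positionwise edit to a serialized signal.
edit_signal <- function(signal, positions, new_degrees) {
  d <- signal_to_degrees(signal)[[1]]
  d[positions] <- new_degrees
  degrees_to_signal(d)
}
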