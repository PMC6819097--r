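#' Read and write game-log CSV files
#'
#' The game-log CSV dialect: UTF-8, comma-separated, header required, one
#' row per trial with columns `participant_id`, `game_id`, `trial`,
#' `sender_role` (`participant` or `confederate`), `state`, `signal` (five
#' space-separated scale degrees in one field), `guess`, `correct` (0/1).
#' Parsing validates the schema and the consistency `correct == (state ==
#' guess)`; offending rows are reported with their line numbers. A
#' serialize-then-read round trip is the identity.
#'
#' @param path CSV path.
#' @return `read_game_logs`: a validated tibble of trials (all games and
#'   participants in the file); split per participant/game with
#'   [split_logs()]. `write_game_logs`: the path, invisibly.
#' @export
read_game_logs <- function(path) {
  log <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    game_id = readr::col_integer(),
    trial = readr::col_integer(),
    sender_role = readr::col_character(),
    state = readr::col_character(),
    signal = readr::col_character(),
    guess = readr::col_character(),
    correct = readr::col_integer()
  ))
  validate_game_log(log)
  log
}

#' @rdname read_game_logs
#' @param log A game-log tibble.
#' @export
write_game_logs <- function(log, path) {
  validate_game_log(log)
  readr::write_csv(log, path)
  invisible(path)
}

#' Validate a game-log tibble
#'
#' @param log A game-log tibble.
#' @return The log, invisibly; stops with row numbers on schema violations.
#' @export
validate_game_log <- function(log) {
  need <- c("participant_id", "game_id", "trial", "sender_role", "state",
            "signal", "guess", "correct")
  missing_cols <- setdiff(need, names(log))
  if (length(missing_cols)) {
    stop("game log missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_role <- which(!log$sender_role %in% c("participant", "confederate"))
  bad_state <- which(!log$state %in% emotions() | !log$guess %in% emotions())
  bad_sig <- which(vapply(signal_to_degrees(log$signal),
                          function(d) length(d) != 5 || anyNA(d), logical(1)))
  bad_correct <- which(log$correct != as.integer(log$state == log$guess))
  problems <- c(
    if (length(bad_role)) paste("invalid sender_role at row(s):",
                                paste(bad_role, collapse = ", ")),
    if (length(bad_state)) paste("unknown emotion at row(s):",
                                 paste(bad_state, collapse = ", ")),
    if (length(bad_sig)) paste("malformed signal at row(s):",
                               paste(bad_sig, collapse = ", ")),
    if (length(bad_correct)) paste("correct flag inconsistent with state/",
                                   "guess at row(s): ",
                                   paste(bad_correct, collapse = ", "))
  )
  if (length(problems)) stop(paste(problems, collapse = "\n"), call. = FALSE)
  dup <- duplicated(log[c("participant_id", "game_id", "trial")])
  if (any(dup)) {
    stop("duplicate trial index at row(s): ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  }
  invisible(log)
}

#' Split a combined log into per-participant, per-game logs
#'
#' @param log A combined game-log tibble.
#' @return Named list `participant_id` -> list of game tibbles (`g1`, `g2`).
#' @export
split_logs <- function(log) {
  ids <- unique(log$participant_id)
  stats::setNames(lapply(ids, function(id) {
    lg <- log[log$participant_id == id, , drop = FALSE]
    list(g1 = lg[lg$game_id == 1L, , drop = FALSE],
         g2 = lg[lg$game_id == 2L, , drop = FALSE])
  }), ids)
}

#' Read and write connectivity-profile CSV files
#'
#' Long format: `participant_id`, `pair` (one of the six ROI-pair labels),
#' `z` (Fisher-z connectivity).
#'
#' @param path CSV path.
#' @return `read_fc_profiles`: a tibble; `write_fc_profiles`: the path,
#'   invisibly.
#' @export
read_fc_profiles <- function(path) {
  fc <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    pair = readr::col_character(),
    z = readr::col_double()
  ))
  bad <- which(!fc$pair %in% fc_pair_labels() | !is.finite(fc$z))
  if (length(bad)) {
    stop("invalid ROI pair or non-finite z at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fc
}

#' @rdname read_fc_profiles
#' @param fc A connectivity tibble.
#' @export
write_fc_profiles <- function(fc, path) {
  readr::write_csv(fc, path)
  invisible(path)
}

#' Write a cohort bundle to a directory
#'
#' Emits the three pipeline CSVs: `game_logs.csv`, `fc_profiles.csv`,
#' `participants.csv` (plus `seed_codes.csv`).
#'
#' @param cohort A [simulate_cohort()] bundle.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- c(
    logs = file.path(dir, "game_logs.csv"),
    fc = file.path(dir, "fc_profiles.csv"),
    participants = file.path(dir, "participants.csv"),
    seed_codes = file.path(dir, "seed_codes.csv")
  )
  write_game_logs(cohort$logs, p[["logs"]])
  write_fc_profiles(cohort$fc, p[["fc"]])
  readr::write_csv(cohort$participants, p[["participants"]])
  seeds <- dplyr::bind_rows(lapply(names(cohort$seed_codes), function(s) {
    dplyr::mutate(cohort$seed_codes[[s]], seed_set = s, .before = 1)
  }))
  readr::write_csv(seeds, p[["seed_codes"]])
  invisible(p)
}

#' Read a cohort bundle from a directory
#'
#' @param dir Directory written by [write_cohort()].
#' @return A bundle list matching [simulate_cohort()]'s shape.
#' @export
read_cohort <- function(dir) {
  seeds <- readr::read_csv(file.path(dir, "seed_codes.csv"),
                           col_types = readr::cols(
                             seed_set = readr::col_character(),
                             emotion = readr::col_character(),
                             signal = readr::col_character()
                           ))
  list(
    participants = readr::read_csv(file.path(dir, "participants.csv"),
                                   col_types = readr::cols(
                                     participant_id = readr::col_character()
                                   )),
    logs = read_game_logs(file.path(dir, "game_logs.csv")),
    fc = read_fc_profiles(file.path(dir, "fc_profiles.csv")),
    seed_codes = stats::setNames(
      lapply(unique(seeds$seed_set), function(s) {
        seeds[seeds$seed_set == s, c("emotion", "signal")]
      }),
      unique(seeds$seed_set)
    )
  )
}
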