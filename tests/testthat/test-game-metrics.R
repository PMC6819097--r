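seed_A <- make_seed_codes()$A

test_that("hamming similarity counts pointwise matches", {
  expect_equal(hamming_similarity(c(0, 4, 6, 7, 10), c(0, 4, 6, 7, 10)), 1)
  expect_equal(hamming_similarity(c(0, 4, 6, 7, 10), c(4, 6, 7, 10, 0)), 0)
  expect_equal(hamming_similarity(c(0, 4, 6, 7, 10), c(0, 4, 6, 7, 4)), 0.8)
  expect_equal(hamming_similarity(c(1, 0, -1, 0), c(1, 0, -1, 0)), 1)
  expect_equal(hamming_distance(c(0, 4, 6, 7, 10), c(0, 4, 6, 7, 4)), 0.2)
  expect_error(hamming_similarity(1:5, 1:4), "equal length")
})

test_that("modal_code tallies the plurality signal per emotion", {
  g1 <- scripted_game1(seed_A)
  mc <- modal_code(g1, "sender")
  expect_equal(mc$signal, seed_A$signal)
  expect_equal(mc$count, mc$n_contributing)

  # brute-force oracle on a random receiver tally (no ties by construction)
  set.seed(11)
  g <- random_log(200)
  mc <- suppressWarnings(modal_code(g, "receiver"))
  for (e in emotions()) {
    sigs <- g$signal[g$guess == e]
    if (length(sigs) == 0) next
    tab <- sort(table(sigs), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) next  # skip ties here
    expect_equal(mc$signal[mc$emotion == e], names(tab)[1])
  }
})

test_that("modal ties break by earliest attainment of the maximal count", {
  x <- "0 4 6 7 10"; y <- "4 4 4 4 4"
  log <- make_log(state = rep("peace", 5),
                  signal = c(x, y, y, x, x),
                  guess = rep("joy", 5))
  # y reaches count 2 at trial 3, x only at trial 4 -> y wins despite the
  # final counts being 3 vs 2 for x ... make counts equal first:
  log <- log[1:4, ]  # x:2 (attained trial 4), y:2 (attained trial 3)
  mc <- suppressWarnings(modal_code(log, "sender"))
  expect_equal(mc$signal[mc$emotion == "peace"], y)
})

test_that("missing emotions are flagged with a warning", {
  log <- make_log(state = rep("peace", 4), signal = rep("0 0 0 0 0", 4),
                  guess = rep("peace", 4))
  expect_warning(mc <- modal_code(log, "sender"), "no contributing")
  expect_true(all(mc$flagged[mc$emotion != "peace"]))
  expect_true(is.na(mc$signal[mc$emotion == "joy"]))
})

test_that("coordination is 1 for a perfect receiver and 0 for a disjoint one", {
  perfect <- scripted_game1(seed_A)
  expect_equal(coordination(perfect, "tone")$mean, 1)
  expect_equal(coordination(perfect, "tone", "modal")$mean, 1)
  # receiver systematically attributes every signal to the next emotion
  # over: heard signals for e are the seed signal of the rotated state
  rot <- c(emotions()[-1], emotions()[1])
  g <- scripted_game1(seed_A, guess_fun = function(state, trial) {
    rot[match(state, emotions())]
  })
  per <- coordination(g, "tone")$per_emotion
  oracle <- vapply(seq_along(emotions()), function(i) {
    heard <- seed_A$signal[match(emotions()[i], rot)]
    hamming_similarity(signal_to_degrees(seed_A$signal[i])[[1]],
                       signal_to_degrees(heard)[[1]])
  }, numeric(1))
  expect_equal(unname(per), oracle)
})

test_that("coordination matches a brute-force loop on a mixed log", {
  set.seed(21)
  g <- scripted_game1(seed_A, guess_fun = function(state, trial) {
    if (stats::runif(1) < 0.6) state else sample(emotions(), 1)
  })
  got <- coordination(g, "tone", "set_mean", window = 36:70)
  # independent brute force over second-half trials
  half <- g[g$trial >= 36 & g$trial <= 70, ]
  per <- numeric(0)
  for (e in emotions()) {
    s <- strsplit(seed_A$signal[seed_A$emotion == e], " ")[[1]]
    heard <- half$signal[half$guess == e]
    if (length(heard) == 0) next
    sims <- sapply(strsplit(heard, " "), function(h) mean(h == s))
    per <- c(per, mean(sims))
  }
  expect_equal(got$mean, mean(per))

  got_c <- coordination(g, "contour", "set_mean", window = 36:70)
  perc <- numeric(0)
  for (e in emotions()) {
    s <- contour_transform(signal_to_degrees(
      seed_A$signal[seed_A$emotion == e])[[1]])
    heard <- half$signal[half$guess == e]
    if (length(heard) == 0) next
    sims <- sapply(signal_to_degrees(heard),
                   function(h) mean(contour_transform(h) == s))
    perc <- c(perc, mean(sims))
  }
  expect_equal(got_c$mean, mean(perc))
})

test_that("transmission reflects positionwise code fidelity", {
  g2_same <- scripted_game2(seed_A)
  expect_equal(transmission(seed_A, g2_same, "tone")$mean, 1)

  # change 2 of 5 positions in each signal -> tone similarity 0.6
  changed <- seed_A
  swap <- function(d) if (d == 0L) 10L else 0L
  changed$signal <- vapply(changed$signal, function(s) {
    d <- signal_to_degrees(s)[[1]]
    d[1] <- swap(d[1]); d[3] <- swap(d[3])
    degrees_to_signal(d)
  }, character(1), USE.NAMES = FALSE)
  g2 <- scripted_game2(changed)
  expect_equal(transmission(seed_A, g2, "tone")$mean, 0.6)
  expect_equal(transmission(seed_A, g2, "tone", "all_trials")$mean, 0.6)

  # entirely different code at every position -> 0
  anti <- seed_A
  anti$signal <- vapply(anti$signal, function(s) {
    d <- signal_to_degrees(s)[[1]]
    degrees_to_signal(ifelse(d == 0L, 4L, ifelse(d == 10L, 0L, d + 3L)))
  }, character(1), USE.NAMES = FALSE)
  g2a <- scripted_game2(anti)
  expect_equal(transmission(seed_A, g2a, "tone")$mean, 0)
})

test_that("innovation is the within-player modal-code distance", {
  g1 <- scripted_game1(seed_A)            # learned code = seed code
  g2_same <- scripted_game2(seed_A)
  expect_equal(innovation(g1, g2_same, "tone")$mean, 0)

  one_off <- seed_A
  one_off$signal <- vapply(one_off$signal, function(s) {
    d <- signal_to_degrees(s)[[1]]
    d[2] <- if (d[2] == 7L) 4L else 7L
    degrees_to_signal(d)
  }, character(1), USE.NAMES = FALSE)
  g2 <- scripted_game2(one_off)
  expect_equal(innovation(g1, g2, "tone")$mean, 0.2)
})

test_that("transmission similarity and innovation distance are complementary", {
  # when the learned code equals the seed code, per-emotion similarity and
  # distance against the same Game-2 modal code sum to 1
  set.seed(31)
  g1 <- scripted_game1(seed_A)
  for (i in 1:10) {
    code <- seed_A
    code$signal <- vapply(code$signal, function(s) {
      d <- signal_to_degrees(s)[[1]]
      k <- sample(0:5, 1)
      if (k > 0) d[sample(5, k)] <- sample(bp_scale_config()$allowed_degrees,
                                           k, replace = TRUE)
      degrees_to_signal(d)
    }, character(1), USE.NAMES = FALSE)
    g2 <- scripted_game2(code)
    tr <- transmission(seed_A, g2, "tone")$per_emotion
    inn <- innovation(g1, g2, "tone")$per_emotion
    expect_equal(unname(tr + inn), rep(1, 5))
  }
})

test_that("asymmetry tracks the direction of code changes", {
  # fixed sender code, receiver revises -> -1 by design
  g <- scripted_game1(seed_A, guess_fun = function(state, trial) {
    if (trial <= 10) "peace" else state
  })
  expect_equal(asymmetry(g), -1)

  # sender revises, receiver never does -> +1
  e <- emotions()
  gs <- make_log(state = rep(e[1], 4),
                 signal = c("0 0 0 0 0", "0 0 0 0 0", "4 4 4 4 4",
                            "4 4 4 4 4"),
                 guess = rep(e[2], 4))
  expect_equal(asymmetry(gs), 1)

  # constructed log with S = 3, R = 7 -> (3 - 7) / 10 = -0.4
  A <- "0 0 0 0 0"; A2 <- "0 0 0 0 4"; B <- "4 4 4 4 4"; B2 <- "4 4 4 4 0"
  C <- "6 6 6 6 6"; C2 <- "6 6 6 6 0"
  log <- make_log(
    state  = c(rep(e[1], 5), rep(e[2], 5), rep(e[3], 4)),
    signal = c(A, A, A, A2, A2,  B, B, B, B2, B2,  C, C, C2, C2),
    guess  = c(e[1], e[2], e[2], e[1], e[2],
               e[1], e[2], e[1], e[1], e[2],
               e[1], e[2], e[1], e[2])
  )
  # sender changes: A->A2, B->B2, C->C2 (3); receiver changes: trials 2, 5,
  # 7, 8, 10, 12, 14 (7)
  expect_equal(asymmetry(log), -0.4)

  # no changes at all -> undefined
  g0 <- make_log(state = rep(e[1], 3), signal = rep(A, 3),
                 guess = rep(e[1], 3))
  expect_warning(a <- asymmetry(g0), "undefined")
  expect_true(is.na(a))
})

test_that("accuracy counts correct trials", {
  g <- scripted_game1(seed_A)
  expect_equal(accuracy(g), 70)
  g_bad <- scripted_game1(seed_A, guess_fun = function(state, trial) {
    setdiff(emotions(), state)[1]
  })
  expect_equal(accuracy(g_bad), 0)
  set.seed(5)
  g_mix <- scripted_game1(seed_A, guess_fun = function(state, trial) {
    if (trial %% 3 == 0) setdiff(emotions(), state)[1] else state
  })
  expect_equal(accuracy(g_mix), sum(seq_len(70) %% 3 != 0))
})

test_that("shannon entropy matches the seeding profile and its bounds", {
  expect_equal(shannon_entropy(c(1, 1, -1, -1)), 1)
  expect_equal(round(shannon_entropy(c(1, 1, 1, -1)), 2), 0.81)
  expect_equal(shannon_entropy(c(0, 0, 0, 0)), 0)
  expect_error(shannon_entropy(character(0)), "empty")
  set.seed(9)
  for (i in 1:30) {
    x <- sample(c(-1, 0, 1), 4, replace = TRUE)
    expect_equal(shannon_entropy(sample(x)), shannon_entropy(x))
    expect_lte(shannon_entropy(x), log2(length(unique(x))) + 1e-12)
    expect_gte(shannon_entropy(x), 0)
  }
})

test_that("mean code entropy averages per-signal entropies", {
  expect_equal(round(mean_code_entropy(seed_A, "contour"), 4),
               round((2 * 1 + 2 * -(0.75 * log2(0.75) + 0.25 * log2(0.25)) +
                        0) / 5, 4))
  mono <- tibble::tibble(emotion = emotions(),
                         signal = rep("6 6 6 6 6", 5))
  expect_equal(mean_code_entropy(mono, "tone"), 0)
  distinct <- tibble::tibble(emotion = emotions(),
                             signal = rep("0 4 6 7 10", 5))
  expect_equal(mean_code_entropy(distinct, "tone"), log2(5))
})

test_that("regularization deltas follow the declared sign conventions", {
  expect_equal(regularization_delta(0.5, 0.5, "entropy"), 0)
  expect_equal(round(regularization_delta(0.724, 0.654, "entropy"), 2), 0.07)
  expect_equal(regularization_delta(1.0, 1.15, "icr"), 0.15)
  expect_true(is.na(regularization_delta(NA_real_, 1, "entropy")))
})

test_that("all bounded measures stay in range over random synthetic logs", {
  set.seed(77)
  sc <- make_seed_codes()
  unit <- matrix(NA_real_, 1000, 3)
  asym <- numeric(1000)
  for (i in 1:1000) {
    g1 <- random_log(70)
    g2 <- random_log(30, game_id = 2L)
    suppressWarnings({
      unit[i, ] <- c(coordination(g1, "tone")$mean,
                     transmission(sc$A, g2, "tone")$mean,
                     innovation(g1, g2, "contour")$mean)
      asym[i] <- asymmetry(g1)
    })
  }
  expect_true(all(unit >= 0 & unit <= 1, na.rm = TRUE))
  expect_true(all(asym >= -1 & asym <= 1, na.rm = TRUE))
})
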