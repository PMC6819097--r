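test_that("seed codes carry the prescribed contour-entropy profile", {
  sc <- make_seed_codes()
  for (set in sc) {
    h <- vapply(set$signal, sequence_entropy, numeric(1),
                distance_mode = "contour", USE.NAMES = FALSE)
    expect_equal(round(h, 2), c(1, 1, 0.81, 0.81, 0))
    degs <- unlist(signal_to_degrees(set$signal))
    expect_true(all(degs %in% c(0, 4, 6, 7, 10)))
  }
  # sets differ in tone content
  d_ab <- mapply(function(a, b) {
    hamming_distance(signal_to_degrees(a)[[1]], signal_to_degrees(b)[[1]])
  }, sc$A$signal, sc$B$signal)
  expect_true(all(d_ab > 0))
})

test_that("an unbeatable learner plays a perfect Game 1", {
  sc <- make_seed_codes()
  set.seed(2)
  g <- simulate_game1(participant_params(ability = 50), sc$A)
  expect_equal(accuracy(g), 70)
  expect_equal(nrow(g), 70)
  # confederate code fixed throughout
  expect_equal(nrow(unique(g[c("state", "signal")])), 5)
  # balanced states: 14 exposures each
  expect_equal(unname(table(g$state)[emotions()]), rep(14L, 5),
               ignore_attr = TRUE)
})

test_that("a non-learner stays at chance accuracy", {
  sc <- make_seed_codes()
  set.seed(4)
  acc <- replicate(200, {
    accuracy(simulate_game1(participant_params(learn_rate = 0), sc$A))
  })
  # Binomial(70, 0.2): mean 14, sd of the mean of 200 games ~ 0.24
  expect_lt(abs(mean(acc) - 14), 1)
})

test_that("simulated Game-1 asymmetry is -1 whenever the receiver revises", {
  sc <- make_seed_codes()
  set.seed(8)
  for (i in 1:20) {
    g <- simulate_game1(participant_params(ability = rnorm(1)), sc$A)
    revised <- anyDuplicated(unique(g[c("signal", "guess")])$signal) > 0
    a <- suppressWarnings(asymmetry(g))
    if (revised) expect_equal(a, -1)
  }
})

test_that("game 2 reproduces, mutates or regularizes the learned code", {
  sc <- make_seed_codes()
  learned <- sc$A
  set.seed(12)
  # no innovation: faithful transmission
  g2 <- simulate_game2(participant_params(innovation_rate = 0), learned)
  expect_equal(transmission(sc$A, g2, "tone")$mean, 1)
  g1 <- scripted_game1(sc$A)
  expect_equal(innovation(g1, g2, "tone")$mean, 0)
  # full innovation with full copy-left bias: monotone signals, contour H=0
  g2r <- simulate_game2(participant_params(innovation_rate = 1,
                                           regularization_bias = 1), learned)
  code <- modal_code(g2r, "sender")
  for (s in code$signal) {
    expect_equal(length(unique(signal_to_degrees(s)[[1]])), 1)
  }
  expect_equal(mean_code_entropy(code, "contour"), 0)
})

test_that("transmission falls as the innovation rate rises", {
  sc <- make_seed_codes()
  set.seed(31)
  mean_tr <- vapply(c(0, 0.2, 0.4, 0.6), function(rate) {
    mean(replicate(60, {
      g2 <- simulate_game2(participant_params(innovation_rate = rate), sc$A)
      transmission(sc$A, g2, "tone")$mean
    }))
  }, numeric(1))
  expect_true(all(diff(mean_tr) < 0))
})

test_that("contour regularization grows in trend with the copy-left bias", {
  # sparse copy-left moves first add the repeat symbol to the contour
  # alphabet (raising entropy) before flattening it, so the response is
  # monotone in trend, with the dominant rise in the upper bias range
  sc <- make_seed_codes()
  set.seed(32)
  h1 <- mean_code_entropy(sc$A, "contour")
  biases <- c(0, 1 / 3, 2 / 3, 1)
  mean_delta <- vapply(biases, function(bias) {
    mean(replicate(80, {
      g2 <- simulate_game2(participant_params(innovation_rate = 0.75,
                                              regularization_bias = bias),
                           sc$A)
      h2 <- mean_code_entropy(modal_code(g2, "sender"), "contour")
      regularization_delta(h1, h2, "entropy")
    }))
  }, numeric(1))
  expect_gt(unname(coef(lm(mean_delta ~ biases))[2]), 0)
  expect_gt(mean_delta[4], mean_delta[1])
  expect_gt(mean_delta[4], mean_delta[2])
})

test_that("accuracy rank-correlates with latent ability", {
  sc <- make_seed_codes()
  set.seed(41)
  abil <- rnorm(200)
  acc <- vapply(abil, function(a) {
    accuracy(simulate_game1(participant_params(ability = a), sc$A))
  }, numeric(1))
  expect_gt(cor(abil, acc, method = "spearman"), 0.5)
})

test_that("connectivity profiles follow the linear-Gaussian model", {
  set.seed(51)
  # zero loadings: independence from ability
  spec0 <- cohort_spec(n_participants = 1000)
  spec0$fc_loadings[] <- 0
  abil <- rnorm(1000)
  fc <- simulate_fc(abil, spec0)
  for (p in fc_pair_labels()) {
    expect_lt(abs(cor(fc$z[fc$pair == p], abil)), 0.1)
  }
  # closed form: corr(z, ability) = beta / sqrt(beta^2 + sigma^2)
  beta <- loading_for_r(0.4, 0.5)
  spec1 <- cohort_spec(n_participants = 2000, fc_noise_sd = 0.5)
  spec1$fc_loadings[] <- beta
  abil2 <- rnorm(2000)
  fc2 <- simulate_fc(abil2, spec1)
  r_hat <- cor(fc2$z[fc2$pair == "lSTG-rSTG"], abil2)
  expect_lt(abs(r_hat - 0.4), 0.05)
})

test_that("cohorts are reproducible and correctly sized", {
  spec <- cohort_spec(n_participants = 6, master_seed = 77)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a, b)
  expect_equal(nrow(a$participants), 6)
  expect_equal(sort(unique(a$participants$seed_set)), c("A", "B"))
  expect_equal(sum(a$logs$game_id == 1), 6 * 70)
  expect_equal(sum(a$logs$game_id == 2), 6 * 30)
  expect_equal(nrow(a$fc), 6 * 6)
  m <- cohort_measures(a)
  expect_equal(nrow(m), 6)
})

test_that("study-scale cohorts have N = 51 and full-length logs", {
  coh <- simulate_cohort(cohort_spec(master_seed = 2))
  expect_equal(nrow(coh$participants), 51)
  expect_equal(nrow(coh$logs), 51 * 100)
  per <- table(coh$logs$participant_id, coh$logs$game_id)
  expect_true(all(per[, "1"] == 70))
  expect_true(all(per[, "2"] == 30))
})
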