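test_that("forward recursion matches exhaustive hidden-sequence marginalization", {
  for (n in c(1, 5, 10)) {
    seqs <- all_sequences(n)
    for (p_d in unlist(study_conditions)) {
      lp <- likelihood_dms(seqs, p_r = 0.9, p_d = p_d)
      oracle <- brute_log_dms(n, 0.9, p_d)
      expect_lt(max(abs(exp(lp) - exp(oracle)) / exp(oracle)), 1e-12)
    }
  }
})

test_that("DMS likelihood normalizes, and degenerate limits hit their closed forms", {
  seqs <- all_sequences(10)
  expect_equal(sum(exp(likelihood_dms(seqs, 0.9, 0.2))), 1, tolerance = 1e-12)

  # p_d = 0.5: emissions are uninformative, every sequence equally likely
  set.seed(31)
  s <- random_sequences(50, 20)
  expect_identical(likelihood_dms(s, 0.9, 0.5), rep(-20 * log(2), 50))

  # p_d = 0: pure Markov closed form from the repetition count R
  R <- rowSums(s[, -1] == s[, -20])
  closed <- log(0.5) + R * log(0.9) + (19 - R) * log(0.1)
  expect_equal(likelihood_dms(s, 0.9, 0), closed, tolerance = 1e-12)

  # impossible sequence has probability zero
  expect_identical(likelihood_dms(c(0, 1, 0, 1), p_r = 1, p_d = 0), -Inf)
})

test_that("DMS likelihood is invariant to color complement and reversal", {
  set.seed(32)
  s <- random_sequences(200, 20)
  lp <- likelihood_dms(s, 0.9, 0.1)
  expect_identical(likelihood_dms(1L - s, 0.9, 0.1), lp)
  expect_equal(likelihood_dms(s[, 20:1], 0.9, 0.1), lp, tolerance = 1e-12)
})

test_that("random-generator likelihood is uniform", {
  expect_equal(likelihood_random(matrix(1L, 1, 1)), log(0.5))
  set.seed(33)
  s <- random_sequences(10, 20)
  expect_identical(likelihood_random(s), rep(20 * log(0.5), 10))
})

test_that("posterior odds implement the lambda > L rule with ties to RANDOM", {
  po <- posterior_odds("11111111111111111111", 0.9, 0.1)
  expect_gt(po$lambda, 1)
  expect_equal(as.character(po$decision), "DMS")
  expect_equal(po$lambda, exp(po$log_p_dms - po$log_p_random))

  # collapse: lambda identically 1, tie resolves to RANDOM
  set.seed(34)
  po5 <- posterior_odds(random_sequences(100, 20), 0.9, 0.5)
  expect_true(all(po5$lambda == 1))
  expect_true(all(po5$decision == "RANDOM"))

  # p_d = 0: the decision is an upper threshold on the repetition count,
  # verified against the closed-form lambda over every R in 0..19
  seqs <- t(vapply(0:19, function(R) {
    s <- integer(20); s[1] <- 0L
    # R repetitions placed first, then alternations
    for (t in 2:20) s[t] <- if (t - 1 <= R) s[t - 1] else 1L - s[t - 1]
    s
  }, integer(20)))
  po0 <- posterior_odds(seqs, 0.9, 0)
  lam_closed <- exp(log(0.5) + (0:19) * log(0.9) + (19 - (0:19)) * log(0.1) -
                      20 * log(0.5))
  expect_equal(po0$lambda, lam_closed, tolerance = 1e-10)
  dec_closed <- lam_closed > 1
  expect_identical(po0$decision == "DMS", dec_closed)
  expect_true(all(diff(as.integer(po0$decision)) >= 0))  # monotone in R
})

test_that("exact performance agrees with large-sample Monte Carlo simulation", {
  ex <- exact_performance(ideal_observer(0.9, 0.1, n = 8))
  set.seed(35)
  nrep <- 100000
  sig <- generate_dms(nrep, 8, 0.9, 0.1)
  noi <- generate_random(nrep, 8)
  io <- ideal_observer(0.9, 0.1, n = 8)
  h <- mean(predict(io, sig) == "DMS")
  f <- mean(predict(io, noi) == "DMS")
  expect_lt(abs(h - ex$hit_rate), 4 * sqrt(ex$hit_rate * (1 - ex$hit_rate) / nrep))
  expect_lt(abs(f - ex$fa_rate), 4 * sqrt(ex$fa_rate * (1 - ex$fa_rate) / nrep))
  expect_gte(ex$hit_rate, ex$fa_rate)  # likelihood-ratio rule optimality
  expect_true(ex$hit_rate >= 0 && ex$hit_rate <= 1)
})

test_that("collapse condition yields chance exact performance", {
  ex <- exact_performance(ideal_observer(0.9, 0.5, n = 12))
  expect_identical(ex$hit_rate, ex$fa_rate)
  expect_identical(ex$d_prime, 0)
})

test_that("Monte Carlo performance is reproducible and consistent with exact", {
  io <- ideal_observer(0.9, 0.1, n = 12)
  a <- mc_performance(io, 3000, seed = 5)
  b <- mc_performance(io, 3000, seed = 5)
  expect_identical(a, b)
  ex <- exact_performance(io)
  se_h <- sqrt(ex$hit_rate * (1 - ex$hit_rate) / 3000)
  se_f <- sqrt(ex$fa_rate * (1 - ex$fa_rate) / 3000)
  expect_lt(abs(a$hit_rate - ex$hit_rate), 4 * se_h)
  expect_lt(abs(a$fa_rate - ex$fa_rate), 4 * se_f)
})

test_that("enumeration beyond the cap and invalid inputs are rejected", {
  expect_error(exact_performance(ideal_observer(0.9, 0.1, n = 25)),
               "enumeration")
  expect_error(likelihood_dms("0011", p_d = 1.5), "probability")
  expect_error(likelihood_dms("0021"), "tokens")
  expect_error(posterior_odds("0011", criterion = -1), "positive")
})
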