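test_that("exact feature distributions normalize and match binomial identities", {
  d3 <- exact_feature_distribution("f3", 0.9, 0.1, n = 20)
  expect_equal(sum(d3$p_random), 1, tolerance = 1e-12)
  expect_equal(sum(d3$p_dms), 1, tolerance = 1e-12)
  # repetitions of an iid fair sequence are 19 independent fair indicators
  expect_equal(d3$p_random, dbinom(d3$support, 19, 0.5), tolerance = 1e-12)
  d4 <- exact_feature_distribution("f4", 0.9, 0.1, n = 20)
  expect_equal(d4$p_random[d4$support == 0], choose(20, 10) / 2^20,
               tolerance = 1e-12)
})

test_that("exact f1 distribution matches Monte Carlo sampling histograms", {
  d <- exact_feature_distribution("f1", 0.9, 0.1, n = 10)
  set.seed(51)
  nrep <- 100000
  for (gen in c("random", "dms")) {
    s <- if (gen == "random") generate_random(nrep, 10)
         else generate_dms(nrep, 10, 0.9, 0.1)
    emp <- tabulate(factor(longest_run(s), levels = d$support),
                    nbins = length(d$support)) / nrep
    p <- if (gen == "random") d$p_random else d$p_dms
    se <- sqrt(p * (1 - p) / nrep)
    expect_true(all(abs(emp - p) < 4 * se + 1e-12))
  }
})

test_that("the ideal f3 observer is an upper-threshold rule dominated by the full model", {
  fo <- feature_observer("f3", 0.9, 0.1, n = 12)
  # decision region is an upper set of the repetition count
  dms <- fo$dist$support %in% fo$dms_values
  expect_true(all(diff(dms) >= 0))
  d_f3 <- exact_performance(fo)$d_prime
  d_full <- exact_performance(ideal_observer(0.9, 0.1, n = 12))$d_prime
  expect_lte(d_f3, d_full)
  expect_gt(d_f3, 0)
})

test_that("at p_d = 0.5 every feature observer is at chance", {
  fo <- feature_observer("f3", 0.9, 0.5, n = 12)
  expect_length(fo$dms_values, 0)
  set.seed(52)
  expect_true(all(predict(fo, random_sequences(20, 12)) == "RANDOM"))
  expect_identical(exact_performance(fo)$d_prime, 0)
})

test_that("feature values outside the support are rejected", {
  fo <- feature_observer("f3", 0.9, 0.1, n = 12)
  expect_error(predict(fo, strrep("1", 15)), "support")
})

test_that("a null observer yields near-zero slopes and the base-rate intercept", {
  set.seed(53)
  s <- build_session("LD", 2000, seed = 53)
  y <- rbinom(2000, 1, 0.4)
  fit <- feature_glm(y, s, subset = 1:4)
  se <- summary(fit$glm)$coefficients[, "Std. Error"]
  expect_true(all(abs(coef(fit)[-1]) < 4 * se[-1]))
  expect_lt(abs(coef(fit)[1] - qlogis(mean(y))), 4 * se[1])
  expect_true(all(abs(fit$beta_std) < 0.1))
})

test_that("the GLM recovers generative weights from a synthetic observer", {
  set.seed(54)
  s <- build_session("LD", 10000, seed = 54)
  obs <- observer_spec(beta0 = -7, beta = c(f3 = 0.5))
  r <- simulate_observer(obs, s, seed = 540)
  fit <- feature_glm(r, s, subset = 3)
  se <- summary(fit$glm)$coefficients[, "Std. Error"]
  expect_lt(abs(coef(fit)[["f3"]] - 0.5), 4 * se[["f3"]])
  expect_lt(abs(coef(fit)[["(Intercept)"]] - (-7)), 4 * se[["(Intercept)"]])
})

test_that("reported log-likelihood equals the Bernoulli log-likelihood at the fit", {
  set.seed(55)
  s <- build_session("MD", 300, seed = 55)
  obs <- observer_spec(-6, c(f1 = 0.3, f3 = 0.2), lapse = 0.1)
  r <- simulate_observer(obs, s, seed = 550)
  fit <- feature_glm(r, s, subset = c(1, 3))
  y <- as.integer(r$response == "DMS")
  p <- predict(fit)
  expect_equal(fit$loglik, sum(y * log(p) + (1 - y) * log(1 - p)),
               tolerance = 1e-8)
})

test_that("Menard standardized weights are invariant to feature rescaling", {
  set.seed(56)
  s <- build_session("LD", 500, seed = 56)
  obs <- observer_spec(-12, c(f3 = 1))
  r <- simulate_observer(obs, s, seed = 560)
  X <- feature_matrix(s, 3)
  fit1 <- feature_glm(r, X, subset = 3)
  X10 <- X * 10
  fit2 <- feature_glm(r, X10, subset = 3)
  expect_equal(fit1$beta_std, fit2$beta_std, tolerance = 1e-6)
})

test_that("standardized weight grows with the generative weight", {
  set.seed(57)
  std <- vapply(c(0.1, 0.3, 0.8), function(b3) {
    s <- build_session("LD", 2000, seed = round(570 + b3 * 100))
    obs <- observer_spec(-b3 * 12, c(f3 = b3))
    r <- simulate_observer(obs, s, seed = round(5700 + b3 * 100))
    feature_glm(r, s, subset = 3)$beta_std[["f3"]]
  }, 0)
  expect_true(all(diff(std) > 0))
})

test_that("separation and rank deficiency are detected", {
  set.seed(58)
  s <- build_session("LD", 100, seed = 58)
  f3 <- feature_matrix(s, 3)[, "f3"]
  det <- ifelse(f3 >= 10, "DMS", "RANDOM")
  expect_warning(fit <- feature_glm(det, s, subset = 3), "separation")
  expect_true(fit$separation)

  X <- feature_matrix(s, c(3, 4))
  X[, "f4"] <- 2
  expect_error(feature_glm(det, X, subset = c(3, 4)), "rank deficiency")
})

test_that("dominant feature identification, ties, and unreliable calls", {
  set.seed(59)
  s <- build_session("LD", 100, seed = 59)
  obs <- observer_spec(-14.4, c(f3 = 1.2))
  r <- simulate_observer(obs, s, seed = 590)
  fit <- feature_glm(r, s, subset = 1:4)
  dom <- dominant_feature(fit)
  expect_equal(as.character(dom), "f3")
  expect_false(attr(dom, "tie"))

  tied <- fit
  tied$beta_std <- c(f1 = 0.5, f2 = 0.2, f3 = 0.5, f4 = 0.1)
  dom2 <- dominant_feature(tied)
  expect_equal(as.character(dom2), "f1")  # lowest index wins
  expect_true(attr(dom2, "tie"))

  guess <- simulate_observer(observer_spec(0, lapse = 1), s, seed = 591)
  fitg <- feature_glm(guess, s, subset = 1:4)
  expect_false(attr(dominant_feature(fitg), "reliable"))
})
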