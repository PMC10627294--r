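test_that("AICc arithmetic, large-n limit and penalty monotonicity", {
  expect_equal(aicc(-50, 3, 100), 106.25)
  expect_equal(aicc(-50, 3, 1e9), -2 * (-50) + 2 * 3, tolerance = 1e-6)
  expect_lt(aicc(-50, 2, 100), aicc(-50, 3, 100))
  expect_error(aicc(-50, 3, 4), "undefined")
})

test_that("evidence ratios invert the Jeffreys criterion lines", {
  expect_equal(evidence_ratio(0), 1)
  expect_equal(evidence_ratio(2 * log(10)), 10)
  expect_equal(evidence_ratio(2 * log(100)), 100)
  d <- 3.7
  expect_equal(evidence_ratio(d) * evidence_ratio(-d), 1)
})

test_that("subset enumeration produces the 15 canonical models", {
  subs <- enumerate_subsets(4)
  expect_length(subs, 15)
  expect_equal(as.integer(table(nchar(names(subs)))), c(4L, 6L, 4L, 1L))
  expect_true("124" %in% names(subs))
  expect_equal(subs[["124"]], c(1L, 2L, 4L))
  expect_equal(names(subs)[1:4], c("1", "2", "3", "4"))
  expect_length(enumerate_subsets(1), 1)
})

fake_fit_set <- function(logliks, n_obs = 100) {
  subs <- enumerate_subsets(4)
  fits <- lapply(seq_along(subs), function(i) {
    k <- length(subs[[i]]) + 1L
    structure(list(model_id = names(subs)[i], k_params = k,
                   loglik = logliks[i], n_obs = n_obs,
                   aicc = aicc(logliks[i], k, n_obs)),
              class = "feature_glm")
  })
  names(fits) <- names(subs)
  class(fits) <- "feature_glm_set"
  fits
}

test_that("with equal log-likelihoods the smallest model wins on penalty alone", {
  fits <- fake_fit_set(rep(-50, 15))
  tab <- multimodel_table(fits)
  expect_equal(nrow(tab), 15)
  expect_equal(nchar(tab$model[1]), 1)
  expect_equal(min(tab$delta_aicc), 0)
  expect_true(all(tab$evidence_ratio >= 1))
  expect_equal(order(tab$k), seq_len(15))
})

test_that("the evidence-ratio cutoff excludes just beyond the criterion", {
  ll <- rep(-80, 15)
  # two-parameter models all share AICc; push model "2" just past 10:1 and
  # model "3" just inside it relative to the best single-feature model
  fits <- fake_fit_set(ll)
  base <- fits[["1"]]$aicc
  fits[["2"]]$aicc <- base + 2 * log(10) + 1e-6
  fits[["3"]]$aicc <- base + 2 * log(10) - 1e-6
  tab <- multimodel_table(fits, criterion = 10)
  expect_false(tab$supported[tab$model == "2"])
  expect_true(tab$supported[tab$model == "3"])
})

test_that("model table requires a complete subset enumeration", {
  fits <- fake_fit_set(rep(-50, 15))
  fits[["3"]] <- NULL
  expect_error(multimodel_table(fits), "incomplete")
})

test_that("log-likelihood never decreases when a feature is added", {
  set.seed(61)
  s <- build_session("MD", 200, seed = 61)
  obs <- observer_spec(-6, c(f1 = 0.25, f3 = 0.3), lapse = 0.1)
  r <- simulate_observer(obs, s, seed = 610)
  fits <- fit_all_models(r, s)
  subs <- enumerate_subsets(4)
  for (a in names(subs)) for (b in names(subs)) {
    if (all(subs[[a]] %in% subs[[b]]) && a != b)
      expect_gte(fits[[b]]$loglik, fits[[a]]$loglik - 1e-6)
  }
})

test_that("the generative two-feature model is usually the best two-feature fit", {
  set.seed(62)
  wins <- 0L
  n_rep <- 100
  for (i in seq_len(n_rep)) {
    s <- build_session("LD", 100, seed = 6200 + i)
    obs <- observer_spec(-11, c(f1 = 0.45, f3 = 0.55))
    r <- simulate_observer(obs, s, seed = 62000 + i)
    fits <- fit_all_models(r, s)
    two <- vapply(fits[nchar(names(fits)) == 2], `[[`, 0, "aicc")
    wins <- wins + (names(which.min(two)) == "13")
  }
  expect_gt(wins / n_rep, 0.5)
})

test_that("AICc averaging across observers produces one ranked table", {
  set.seed(63)
  cohort <- simulate_cohort(
    list(observer_spec(-10, c(f3 = 0.8), lapse = 0.05),
         observer_spec(-5, c(f1 = 0.4), lapse = 0.05)),
    condition = "LD", n_trials = 100, seed = 63)
  sets <- lapply(cohort, function(ob) fit_all_models(ob$responses, ob$session))
  tab <- multimodel_table(sets)
  expect_equal(nrow(tab), 15)
  single <- vapply(sets, function(f) f[["3"]]$aicc, 0)
  expect_equal(tab$aicc[tab$model == "3"], mean(single), tolerance = 1e-10)
  pars <- attr(tab, "parsimony")
  expect_equal(pars$size, 1:4)
})
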