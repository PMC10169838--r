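make_sim_df <- function(d, v) {
  structure(data.frame(dose_ug_per_ml = d, ternary_nM = v,
                       ternary_normalized = if (max(v) > 0) v / max(v) else v),
            class = c("dose_response", "data.frame"))
}

test_that("normalize_pair is affine-invariant and handles degeneracy", {
  d <- c(0.01, 0.1, 1)
  sim <- make_sim_df(d, c(0.2, 1.0, 0.4))
  # observed = affine transform of simulated -> identical normalized series
  obs <- observed_dose_response("p1", d, 3000 * c(0.2, 1.0, 0.4) + 150)
  np <- normalize_pair(obs, sim)
  expect_equal(np$observed_norm, c(0, 1, 0.25))
  expect_equal(np$simulated_norm, np$observed_norm)
  expect_equal(sse(np$observed_norm, np$simulated_norm), 0,
               tolerance = 1e-12)

  obs2 <- observed_dose_response("p2", c(1, 2), c(0, 10))
  np2 <- normalize_pair(obs2, make_sim_df(c(1, 2), c(0, 5)))
  expect_equal(np2$observed_norm, c(0, 1))
  expect_equal(np2$simulated_norm, c(0, 1))

  expect_error(normalize_pair(observed_dose_response("p3", c(1, 2), c(5, 5)),
                              sim), "degenerate")
  # off-grid doses are interpolated in log dose
  obs3 <- observed_dose_response("p4", sqrt(0.01 * 0.1), 1000)
  expect_error(normalize_pair(obs3, sim), "degenerate")  # single point
  # log-midpoint of the first two grid doses interpolates their values
  obs4 <- observed_dose_response("p4", c(sqrt(0.01 * 0.1), 1), c(10, 20))
  np4 <- normalize_pair(obs4, sim)   # raw sim values (0.6, 0.4) -> (1, 0)
  expect_equal(np4$simulated_norm, c(1, 0))
})

test_that("sse matches hand arithmetic", {
  expect_equal(sse(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(sse(c(0, 1), c(0.5, 0.5)), 0.5)
  expect_equal(sse(c(0, 1), c(1, 0)), sse(c(1, 0), c(0, 1)))
  expect_error(sse(1:3, 1:2), "length")
})

test_that("fit_pair is self-consistent and honours bounds", {
  spec <- synthetic_spec("selfcheck", base_pair_params(), experiment_setup(),
                         sigma = 0, seed = 5)
  truth <- generate_truth(spec)
  obs <- observe(truth, spec)
  fr <- fit_pair(obs, spec$params, spec$setup)
  expect_lt(fr$sse_fitted, 1e-10)          # observed generated from start
  expect_lte(fr$sse_fitted, fr$sse_initial)
  k <- vapply(RN, function(nm) fr$params[[nm]], numeric(1))
  expect_true(all(k >= fr$bounds["lower", ] - 1e-12))
  expect_true(all(k <= fr$bounds["upper", ] + 1e-12))
})

test_that("fitted SSE never exceeds the initial SSE for perturbed starts", {
  set.seed(31)
  spec <- synthetic_spec("mono", base_pair_params(), experiment_setup(),
                         sigma = 0.05, seed = 6)
  obs <- observe(generate_truth(spec), spec)
  for (i in 1:3) {
    lit <- perturbed_params(spec$params, factor = 5)
    fr <- fit_pair(obs, lit, spec$setup, control = list(maxit = 30))
    expect_lte(fr$sse_fitted, fr$sse_initial + 1e-12)
    k <- vapply(RN, function(nm) fr$params[[nm]], numeric(1))
    expect_true(all(k >= fr$bounds["lower", ] - 1e-12 &
                    k <= fr$bounds["upper", ] + 1e-12))
  }
})

test_that("fit_cohort averages, flags outliers, and survives failures", {
  specs <- default_synthetic_specs(seed = 3, sigma = 0)
  specs <- specs[1:4]
  observations <- lapply(specs, function(sp) observe(generate_truth(sp), sp))
  lits <- lapply(specs, `[[`, "params")
  setups <- lapply(specs, `[[`, "setup")

  # cohort of one: averages equal that pair's values
  c1 <- fit_cohort(observations[1], lits[1], setups[1],
                   control = list(maxit = 5))
  expect_equal(c1$mean_sse_initial, c1$fits[[1]]$sse_initial)
  expect_equal(c1$mean_sse_fitted, c1$fits[[1]]$sse_fitted)

  # noise-free cohort started from truth: essentially zero error
  co <- fit_cohort(observations, lits, setups, control = list(maxit = 5))
  expect_lt(co$mean_sse_fitted, 1e-6)
  expect_length(co$outlier_pairs, 0)
  expect_length(co$failed_pairs, 0)

  # one deliberately mis-specified literature set is flagged
  lits_bad <- lits
  lits_bad[[2]] <- set_param(set_param(lits[[2]], "kf1", lits[[2]]$kf1 / 50),
                             "KD2", 500)
  co2 <- fit_cohort(observations, lits_bad, setups,
                    control = list(maxit = 3))
  expect_equal(co2$outlier_pairs, names(observations)[2])
})
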