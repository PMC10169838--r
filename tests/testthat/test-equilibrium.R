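test_that("zero dynamics leave the state constant", {
  # the public constructor requires positive rates; drive the integrator
  # directly with all-zero rate constants
  y0 <- c(0.1, 1, 0.2, 0.05, 0.02, 0.01)
  res <- ternarybinding:::.integrate_kinetics_cpp(y0, rep(0, 8),
                                                  c(0, 1, 1e3, 1e6),
                                                  1e-8, 1e-12, 10000L)
  expect_equal(res$status, 0)
  for (i in 1:4) expect_equal(unname(res$states[i, ]), y0)
})

test_that("single-reaction limit reproduces the 1:1 quadratic isotherm", {
  s <- experiment_setup()
  cases <- list(c(a0 = 1, b0 = 1, kd = 1),
                c(a0 = 0.5, b0 = 2, kd = 0.1),
                c(a0 = 3, b0 = 0.2, kd = 10))
  for (cs in cases) {
    p <- isolated_pair1(kf1 = 1, kr1 = cs[["kd"]])
    tr <- simulate_kinetics(s, p, system_state(Tc = cs[["a0"]],
                                               Ab = cs[["b0"]]))
    expected <- quadratic_bound(cs[["a0"]], cs[["b0"]], cs[["kd"]])
    got <- tr[nrow(tr), "Tc.Ab"]
    expect_lt(abs(got - expected) / expected, 1e-6)
    expect_true(attr(tr, "equilibrium_reached"))
    # the root-finding oracle agrees with the same closed form
    ss <- steady_state_solve(p, c(Tc_total = cs[["a0"]],
                                  Ab_total = cs[["b0"]], Tu_total = 0))
    expect_lt(abs(ss[["Tc.Ab"]] - expected) / expected, 1e-6)
  }
})

test_that("trajectories conserve totals and stay non-negative", {
  set.seed(21)
  s <- experiment_setup()
  tot <- setup_totals(s)
  for (i in 1:20) {
    p <- rand_params()
    ab <- antibody_dose_to_molar(10^runif(1, -4, 1), 150000)
    tr <- simulate_kinetics(s, p, system_state(Tc = tot[["Tc"]], Ab = ab,
                                               Tu = tot[["Tu"]]))
    m <- as.matrix(tr[, -1])
    ct <- apply(m, 1, function(st)
      conserved_totals(setNames(st, colnames(m))))
    drift <- apply(ct, 1, function(x) diff(range(x))) / apply(ct, 1, max)
    expect_lt(max(drift), 1e-8)
    expect_true(all(m >= -1e-12 * max(ct)))
  }
})

test_that("terminal integration state matches the root-finding oracle", {
  set.seed(22)
  s <- experiment_setup()
  tot <- setup_totals(s)
  for (i in 1:30) {
    p <- rand_params()
    ab <- antibody_dose_to_molar(10^runif(1, -4, 1), 150000)
    tr <- simulate_kinetics(s, p, system_state(Tc = tot[["Tc"]], Ab = ab,
                                               Tu = tot[["Tu"]]))
    term <- setNames(as.numeric(tr[nrow(tr), -1]),
                     names(tr)[-1])
    ss <- steady_state_solve(p, c(Tc_total = tot[["Tc"]], Ab_total = ab,
                                  Tu_total = tot[["Tu"]]))
    rel <- abs(term - ss) / (pmax(abs(term), abs(ss)) + 1e-12)
    expect_lt(max(rel), 1e-6)
    # the root really is a fixed point
    expect_lt(max(abs(ode_rhs(ss, p))),
              1e-10 * max(vapply(RN[1:4], function(nm) p[[nm]], 1)) *
                max(tot, ab)^2 + 1e-20)
  }
})

test_that("steady_state_solve handles degenerate totals", {
  p <- base_pair_params()
  ss <- steady_state_solve(p, c(Tc_total = 0.1, Ab_total = 0,
                                Tu_total = 0.2))
  expect_equal(unname(ss[c("Tc.Ab", "Ab.Tu", "Tc.Ab.Tu")]), c(0, 0, 0))
  expect_equal(ss[["Tc"]], 0.1)
  expect_error(steady_state_solve(p, c(Tc_total = 1, Ab_total = -1,
                                       Tu_total = 1)), "non-negative")
})

test_that("equilibrium dose-response is zero at zero dose and unimodal", {
  s <- experiment_setup(dose_grid = c(0, default_dose_grid(n = 30)))
  p <- base_pair_params()
  dr <- equilibrium_dose_response(s, p)
  expect_equal(dr$ternary_nM[1], 0)
  expect_true(is_unimodal(dr$ternary_nM))
  expect_equal(max(dr$ternary_normalized), 1)
  # verification path against the independent root-finder
  expect_no_error(equilibrium_dose_response(
    s, p, doses = default_dose_grid(n = 5), verify = TRUE))
})

test_that("hook_metrics follows its stated rules", {
  mk <- function(d, v) data.frame(dose_ug_per_ml = d, ternary_nM = v)
  h <- hook_metrics(mk(c(1, 2, 3), c(0.1, 0.9, 0.2)))
  expect_equal(h$peak_dose, 2)
  expect_true(h$hook_detected)
  expect_equal(h$effective_window, c(2, 2))

  h2 <- hook_metrics(mk(1:5, c(1, 2, 3, 4, 5)))
  expect_false(h2$hook_detected)
  expect_equal(h2$peak_dose, 5)

  # ties resolve to the smallest dose
  h3 <- hook_metrics(mk(1:4, c(0.1, 1, 1, 0.1)))
  expect_equal(h3$peak_dose, 2)

  h0 <- hook_metrics(mk(1:3, c(0, 0, 0)))
  expect_equal(h0$peak_ternary, 0)
  expect_false(h0$hook_detected)

  # window boundaries match a brute-force linear scan for the 50% crossings
  set.seed(23)
  s <- experiment_setup()
  for (i in 1:5) {
    dr <- equilibrium_dose_response(s, rand_params(),
                                    doses = default_dose_grid(n = 40))
    h <- hook_metrics(dr)
    half <- 0.5 * h$peak_ternary
    above <- which(dr$ternary_nM >= half)
    runs <- split(above, cumsum(c(1, diff(above) != 1)))
    run <- runs[[which(vapply(runs, function(r)
      which.max(dr$ternary_nM) %in% r, TRUE))[1]]]
    expect_equal(h$effective_window,
                 c(dr$dose_ug_per_ml[min(run)], dr$dose_ug_per_ml[max(run)]))
    expect_gte(h$peak_dose, h$effective_window[1])
    expect_lte(h$peak_dose, h$effective_window[2])
  }
})

test_that("integration failure reports the last valid state", {
  s <- experiment_setup(t_max = 1e6)
  p <- base_pair_params()
  tot <- setup_totals(s)
  expect_error(
    simulate_kinetics(s, p, system_state(Tc = tot[["Tc"]], Ab = 1,
                                         Tu = tot[["Tu"]]),
                      max_steps = 3L),
    "integration error")
})
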