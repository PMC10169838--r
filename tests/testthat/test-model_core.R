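test_that("binding_params validates rates and derives KD consistently", {
  p <- binding_params(kf1 = 0.5, kf2 = 2, kf3 = 3, kf4 = 4,
                      kr1 = 0.25, kr2 = 1, kr3 = 6, kr4 = 2,
                      check_balance = FALSE)
  expect_equal(unname(p$KD), c(0.5, 0.5, 2, 0.5))
  # KD_i * kf_i == kr_i to machine tolerance
  for (i in 1:4)
    expect_equal(p$KD[[paste0("KD", i)]] * p[[paste0("kf", i)]],
                 p[[paste0("kr", i)]])
  for (bad in list(list(kf1 = 0), list(kr3 = -1), list(kf2 = Inf),
                   list(kr4 = NaN)))
    expect_error(do.call(binding_params,
                         utils::modifyList(list(kf1 = 1, kf2 = 1, kf3 = 1,
                                                kf4 = 1, kr1 = 1, kr2 = 1,
                                                kr3 = 1, kr4 = 1), bad)),
                 names(bad))
})

test_that("detailed balance is warned about but not enforced", {
  expect_warning(binding_params(1, 1, 1, 1, 1, 1, 1, 100),
                 "detailed balance")
  expect_silent(binding_params(1, 1, 1, 1, 1, 1, 1, 1))
})

test_that("set_param alters rates directly and KD via the reverse rate", {
  p <- params_from_vec(rep(1, 8))
  expect_equal(set_param(p, "kf3", 7)$kf3, 7)
  q <- set_param(p, "KD2", 5)
  expect_equal(q$kf2, 1)       # forward rate untouched
  expect_equal(q$kr2, 5)
  expect_equal(q$KD[["KD2"]], 5)
  expect_error(set_param(p, "kx9", 1), "allowed")
})

test_that("reaction_rates matches hand-written mass-action expressions", {
  # zero state annihilates every flux
  p <- params_from_vec(runif(8, 0.1, 2))
  expect_equal(unname(reaction_rates(system_state(), p)), rep(0, 8))

  # single live reaction: direct substitution
  r <- reaction_rates(system_state(Tc = 1, Ab = 2), isolated_pair1(kf1 = 0.5))
  expect_equal(r[["rxn1"]], 1.0)
  expect_equal(unname(r[-1]), rep(0, 7), tolerance = 1e-25)

  # randomized draws against an independent re-evaluation of each product
  set.seed(11)
  for (i in 1:20) {
    st <- setNames(runif(6, 0, 5), c("Tc", "Ab", "Tu", "Tc.Ab", "Ab.Tu",
                                     "Tc.Ab.Tu"))
    p <- params_from_vec(runif(8, 1e-3, 10))
    expected <- c(p$kf1 * st["Tc"] * st["Ab"], p$kr1 * st["Tc.Ab"],
                  p$kf2 * st["Ab"] * st["Tu"], p$kr2 * st["Ab.Tu"],
                  p$kf3 * st["Tc.Ab"] * st["Tu"], p$kr3 * st["Tc.Ab.Tu"],
                  p$kf4 * st["Tc"] * st["Ab.Tu"], p$kr4 * st["Tc.Ab.Tu"])
    expect_equal(unname(reaction_rates(st, p)), unname(expected))
  }
  expect_error(reaction_rates(system_state(Tc = 1) - 2, p), "Tc")
})

test_that("ode_rhs is the signed flux sum and conserves the three totals", {
  p <- params_from_vec(runif(8, 0.1, 2))
  expect_equal(unname(ode_rhs(system_state(), p)), rep(0, 6))

  d <- ode_rhs(system_state(Tc = 1, Ab = 1), isolated_pair1(kf1 = 1))
  expect_equal(unname(d[c("Tc", "Ab", "Tc.Ab")]), c(-1, -1, 1),
               tolerance = 1e-20)

  set.seed(12)
  for (i in 1:25) {
    st <- setNames(runif(6, 0, 3), c("Tc", "Ab", "Tu", "Tc.Ab", "Ab.Tu",
                                     "Tc.Ab.Tu"))
    p <- rand_params()
    d <- ode_rhs(st, p)
    scale <- max(abs(d), 1e-300)
    expect_lt(abs(d[["Tc"]] + d[["Tc.Ab"]] + d[["Tc.Ab.Tu"]]) / scale, 1e-12)
    expect_lt(abs(d[["Ab"]] + d[["Tc.Ab"]] + d[["Ab.Tu"]] +
                  d[["Tc.Ab.Tu"]]) / scale, 1e-12)
    expect_lt(abs(d[["Tu"]] + d[["Ab.Tu"]] + d[["Tc.Ab.Tu"]]) / scale, 1e-12)
    # compiled right-hand side agrees with the R reference
    k <- vapply(RN, function(nm) p[[nm]], numeric(1))
    expect_equal(unname(ternarybinding:::.ode_rhs_cpp(unname(st), unname(k))),
                 unname(d), tolerance = 1e-14)
  }
})

test_that("bench-unit conversions follow the arithmetic oracles", {
  expect_equal(antibody_dose_to_molar(1, 150000), 6.6667, tolerance = 1e-4)
  expect_equal(antibody_dose_to_molar(0, 150000), 0)
  expect_equal(antibody_dose_to_molar(0.25, 150000), 1.6667, tolerance = 1e-4)
  expect_error(antibody_dose_to_molar(1, 0), "mw")
  expect_error(antibody_dose_to_molar(-1, 1000), "dose")

  expect_equal(sites_to_molar(1e5, 1e4, 1),
               1e5 * 1e4 / (6.02214076e23 * 1e-3) * 1e9, tolerance = 1e-12)
  expect_equal(sites_to_molar(1e5, 1e4, 1), 1.661e-3, tolerance = 1e-3)
  expect_equal(sites_to_molar(2e5, 1e5, 0.2), 0.16606, tolerance = 1e-4)
  expect_equal(sites_to_molar(2e5, 1e4, 1), 2 * sites_to_molar(1e5, 1e4, 1))
  expect_error(sites_to_molar(1e5, 1e4, 0), "volume")
})

test_that("experiment_setup validates its fields", {
  expect_error(experiment_setup(volume_ml = -1), "volume_ml")
  expect_error(experiment_setup(dose_grid = c(2, 1)), "sorted")
  s <- experiment_setup()
  tot <- setup_totals(s)
  expect_equal(unname(tot[["Tu"]] / tot[["Tc"]]), 2)  # 2e5 vs 1e5 cells
})
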