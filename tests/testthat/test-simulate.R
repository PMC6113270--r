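test_that("integration reaches the algebraic fixed point and respects bounds", {
  tr <- simulate_model(p_def, scenario_config(years = 300, output_step = 30))
  fin <- tr$states[nrow(tr$states), ]
  expect_true(all(abs(fin - fp_ref) / fp_ref < 0.005))  # < 0.5% per component
  expect_true(all(tr$states >= 0))
  expect_true(all(tr$states[, "Z"] <= p_def$Z_max * (1 + 1e-6)))
  expect_true(all(tr$states[, "L"] <= p_def$L_max * (1 + 1e-6)))
  expect_equal(unname(tr$states[1, ]),
               unname(default_initial_state <- c(0.01 * p_def$Z_max, 0, 0, 1)))
  expect_true(all(diff(tr$times) > 0))
})

test_that("solutions are solver-independent up to tolerance", {
  base <- scenario_config(years = 100, output_step = 30)
  tight <- scenario_config(years = 100, output_step = 30,
                           rtol = 5e-9, atol = 5e-11)
  for (mut in c(TRUE, FALSE)) {
    base$mutualism <- tight$mutualism <- mut
    a <- simulate_model(p_def, base)
    b <- simulate_model(p_def, tight)
    fa <- a$states[nrow(a$states), ]; fb <- b$states[nrow(b$states), ]
    expect_lt(max(abs(fa - fb) / pmax(abs(fa), 1e-6)), 1e-3)
  }
})

test_that("without the mutualism the bed overshoots, collapses, and oscillates damped", {
  cfg <- scenario_config(mutualism = FALSE, years = 20, output_step = 1)
  tr <- simulate_model(p_def, cfg)
  z <- tr$states[, "Z"]
  expect_gt(max(z), 0.4 * p_def$Z_max)               # transient bloom
  expect_lt(z[length(z)], 0.05 * p_def$Z_max)        # collapse below 5%
  expect_lt(which.max(z), length(z) / 2)             # peak early, then down
  lab <- classify_regime(tr, transient_days = 2 * 365)
  expect_equal(lab$regime, "damped_oscillation")
})

test_that("with the mutualism the bed settles near carrying capacity with buffered sulfide", {
  tr <- simulate_model(p_def, scenario_config(years = 20, output_step = 7))
  z <- tr$states[, "Z"]
  final5 <- z[tr$times > 15 * 365]
  expect_true(all(abs(final5 - fp_ref["Z"]) / fp_ref["Z"] < 0.05))
  lab <- classify_regime(tr, transient_days = 10 * 365)
  expect_equal(lab$regime, "stable_equilibrium")
  # sulfide stays below the toxicity onset once past the initial transient
  expect_true(all(tr$states[tr$times > 10 * 365, "S"] < p_def$S_min))
})

test_that("raised mortality produces sustained slow-fast collapse-recovery cycles", {
  tr <- simulate_model(set_param(p_def, "m_n", 0.03),
                       scenario_config(years = 800, output_step = 14))
  lab <- classify_regime(tr, transient_days = 500 * 365)
  expect_equal(lab$regime, "limit_cycle")
  expect_gt(lab$period_days, 365)            # multi-year cycles
  expect_lt(lab$Z_min, 0.01 * p_def$Z_max)   # bare phase
  expect_gt(lab$Z_max, 0.8 * fp_ref[["Z"]])  # recovered phase
  # label unchanged when the run is twice as long (same absolute transient)
  tr2 <- simulate_model(set_param(p_def, "m_n", 0.03),
                        scenario_config(years = 1100, output_step = 14))
  expect_equal(classify_regime(tr2, transient_days = 500 * 365)$regime,
               "limit_cycle")
})

test_that("regime classifier handles prescribed trajectories and bad input", {
  expect_equal(classify_regime(fake_traj(rep(7840, 400)),
                               transient_days = 100)$regime,
               "stable_equilibrium")
  expect_equal(classify_regime(fake_traj(rep(1, 400)),
                               transient_days = 100)$regime,
               "collapsed")
  # decaying ringing around a mid level -> damped
  t <- seq_len(800)
  z <- 4000 + 2000 * exp(-t / 150) * cos(2 * pi * t / 60)
  expect_equal(classify_regime(fake_traj(z), transient_days = 100 * 14,
                               amplitude_tol = 1e-3)$regime,
               "damped_oscillation")
  # steady ringing -> limit cycle
  z2 <- 4000 + 2000 * cos(2 * pi * t / 60)
  expect_equal(classify_regime(fake_traj(z2), transient_days = 100 * 14)$regime,
               "limit_cycle")
  bad <- fake_traj(c(rep(1, 399), NaN))
  expect_error(classify_regime(bad, transient_days = 100), "non-finite")
  expect_error(classify_regime(fake_traj(rep(1, 10)), transient_days = 1e6),
               "not longer than the transient")
})

test_that("trajectories export to CSV with the documented layout", {
  tr <- simulate_model(p_def, scenario_config(years = 2, output_step = 30))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  d <- utils::read.csv(f)
  expect_identical(names(d), c("t_days", "Z", "S", "OM", "L"))
  expect_equal(nrow(d), length(tr$times))
  expect_equal(d$Z, unname(tr$states[, "Z"]))
})
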