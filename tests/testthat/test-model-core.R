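test_that("toxicity response is the piecewise-linear ramp", {
  expect_equal(toxicity_fraction(100, p_def), 0)
  expect_equal(toxicity_fraction(1000, p_def), 1)
  expect_equal(toxicity_fraction(600, p_def), 0.5)  # (600-200)/(1000-200)
  expect_error(toxicity_fraction(-1, p_def), "non-negative")
  # brute-force pointwise evaluation of the three branches on a dense grid
  S <- seq(0, 2000, by = 0.5)
  brute <- vapply(S, function(s) {
    if (s < p_def$S_min) 0
    else if (s > p_def$S_max) 1
    else (s - p_def$S_min) / (p_def$S_max - p_def$S_min)
  }, numeric(1))
  f <- toxicity_fraction(S, p_def)
  expect_equal(f, brute)
  expect_true(all(diff(f) >= 0))           # non-decreasing
  expect_true(all(f >= 0 & f <= 1))
  expect_lt(max(abs(diff(f))), 1e-3)       # continuous at the breakpoints
})

test_that("mortality flux combines sulfide and background terms linearly in Z", {
  expect_equal(mortality_flux(8000, 0, p_def), 56)        # 0.007 * 8000
  expect_equal(mortality_flux(0, 5000, p_def), 0)
  expect_equal(mortality_flux(1000, 2000, p_def), 507)    # (0.5 + 0.007)*1000
  expect_error(mortality_flux(-1, 0, p_def), "non-negative")
  expect_error(mortality_flux(1, -1, p_def), "non-negative")
  Z <- c(1, 10, 500, 8000)
  expect_equal(mortality_flux(Z, 600, p_def), Z * mortality_flux(1, 600, p_def))
})

test_that("vector field vanishes at bare sediment and at the vegetated fixed point", {
  expect_equal(model_rhs(model_state(), p_def),
               c(Z = 0, S = 0, OM = 0, L = 0))
  d <- model_rhs(fp_ref, p_def)
  expect_true(all(abs(d) < 1e-2))
  # bivalves at carrying capacity on clean sediment decline at m_L * L_max
  d2 <- model_rhs(model_state(Z = 8000, S = 0, OM = 0, L = 4900), p_def)
  expect_equal(unname(d2["L"]), -9.8)
})

test_that("algebraic fixed point matches its defining equations", {
  fp <- high_fixed_point(p_def)
  expect_equal(fp, fp_ref, tolerance = 1e-6)
  expect_lt(fp["S"], p_def$S_min)  # the fS = 0 assumption closes
  d <- model_rhs(fp, p_def)
  expect_true(all(abs(d) < 1e-9))
  expect_error(high_fixed_point(seagrass_params(m_n = 0.4)), "m_n >= r")
})

test_that("mutualism-off field equals the on field with L = 0 and frozen bivalves", {
  set.seed(401)
  for (i in 1:20) {
    st <- model_state(Z = runif(1, 0, 8000), S = runif(1, 0, 2000),
                      OM = runif(1, 0, 1), L = 0)
    on <- model_rhs(st, p_def, mutualism = TRUE)
    off <- model_rhs(st, p_def, mutualism = FALSE)
    expect_equal(off[c("Z", "S", "OM")], on[c("Z", "S", "OM")])
    expect_equal(unname(off["L"]), 0)
  }
})

test_that("the non-negative orthant is forward-invariant on its boundary faces", {
  set.seed(402)
  for (i in 1:40) {
    p <- seagrass_params(Z_max = runif(1, 100, 20000),
                         r = runif(1, 0.01, 1),
                         m_s = runif(1, 0, 1), m_n = runif(1, 0, 0.3),
                         C_s = runif(1, 0, 0.01), e_s = runif(1, 0.01, 1),
                         C_z = runif(1, 1e-7, 1e-5), e_m = runif(1, 1e-4, 0.01),
                         S_min = runif(1, 50, 400), S_max = runif(1, 500, 2000),
                         r_L = runif(1, 1, 50), L_max = runif(1, 100, 10000),
                         m_L = runif(1, 0, 0.05))
    full <- model_state(Z = runif(1, 0, p$Z_max), S = runif(1, 0, 2 * p$S_max),
                        OM = runif(1, 0, 2), L = runif(1, 0, p$L_max))
    for (face in c("Z", "S", "OM", "L")) {
      st <- full; st[face] <- 0
      for (mut in c(TRUE, FALSE)) {
        d <- model_rhs(st, p, mutualism = mut)
        expect_gte(d[[face]], 0)
      }
    }
  }
})

test_that("compiled and pure-R vector fields integrate to the same trajectory", {
  # horizons stop short of the bare-phase floor, where the compiled refuge
  # guard and the plain equations legitimately part ways
  for (case in list(list(p = p_def, mut = TRUE, days = 5 * 365,
                         y0 = c(Z = 80, S = 0, OM = 0, L = 1)),
                    list(p = set_param(p_def, "m_n", 0.03), mut = TRUE,
                         days = 60,
                         y0 = c(Z = 4000, S = 500, OM = 0.2, L = 1000)),
                    list(p = p_def, mut = FALSE, days = 2 * 365,
                         y0 = c(Z = 80, S = 0, OM = 0, L = 0)))) {
    times <- seq(0, case$days, by = case$days / 365)
    ref <- integrate_with_r_rhs(case$p, case$mut, case$y0, times)
    cfg <- scenario_config(mutualism = case$mut, duration_days = case$days,
                           initial_state = case$y0,
                           output_step = case$days / 365)
    got <- simulate_model(case$p, cfg)
    scale <- pmax(abs(ref[, -1]), 1)
    expect_lt(max(abs(got$states - ref[, -1]) / scale), 1e-6)
  }
})
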