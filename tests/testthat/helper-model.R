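# Shared fixtures: everything is generated in code at test time.

p_def <- seagrass_params()

# Reference values of the non-toxic vegetated equilibrium, derived by hand:
# Z* = Z_max (1 - m_n/r); OM* = C_z m_n Z* / e_m; L* from the bivalve
# equation; S* = C_om OM* / (C_s L* + e_s).
fp_ref <- c(Z = 7840, S = 61.93781, OM = 0.1229922, L = 3538.889)

# A trajectory object with prescribed Z values (for classifier unit tests).
fake_traj <- function(z, dt = 14, p = p_def) {
  structure(list(times = seq_along(z) * dt - dt,
                 states = cbind(Z = z, S = 0 * z, OM = 0 * z, L = 0 * z),
                 params = p,
                 config = scenario_config(years = max(length(z) * dt / 365, 1))),
            class = "seagrass_trajectory")
}

# Pure-R integration route used as the independent cross-check of the
# compiled vector field.
integrate_with_r_rhs <- function(p, mutualism, y0, times, rtol = 1e-8,
                                 atol = 1e-10) {
  f <- function(t, y, parms) {
    y <- pmax(y, 0)
    list(unname(model_rhs(c(Z = y[[1]], S = y[[2]], OM = y[[3]], L = y[[4]]),
                          parms, mutualism)))
  }
  deSolve::ode(y = y0, times = times, func = f, parms = p,
               rtol = rtol, atol = atol)
}
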