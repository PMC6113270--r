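#' Scenario configuration
#'
#' Settings for one model integration. The default initial state is a sparse
#' colonising bed (1% of carrying capacity) on clean sediment, with a seed
#' population of one bivalve per square metre when the mutualism is active
#' and none when it is not.
#'
#' @param mutualism Logical; integrate with the bivalve equation active?
#' @param duration_days Length of the run, days. `years` may be given
#'   instead (1 year = 365 days).
#' @param years Convenience alternative to `duration_days`.
#' @param initial_state Named state vector, see [model_state()]; `NULL` for
#'   the default described above.
#' @param output_step Spacing of saved output, days.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(mutualism = TRUE,
                            duration_days = NULL,
                            years = 100,
                            initial_state = NULL,
                            output_step = 7,
                            rtol = 1e-8,
                            atol = 1e-10) {
  if (is.null(duration_days)) duration_days <- years * 365
  if (duration_days <= 0) stop("duration must be positive")
  if (output_step <= 0) stop("output_step must be positive")
  if (output_step > duration_days) stop("output_step exceeds duration")
  structure(list(mutualism = isTRUE(mutualism),
                 duration_days = duration_days,
                 initial_state = initial_state,
                 output_step = output_step,
                 rtol = rtol, atol = atol),
            class = "scenario_config")
}

default_initial_state <- function(p, mutualism) {
  model_state(Z = 0.01 * p$Z_max, S = 0, OM = 0,
              L = if (mutualism) 1 else 0)
}

#' Integrate the model
#'
#' Runs the coupled ODE system with an adaptive stiff-capable solver
#' (`deSolve::lsoda`) over a scenario and returns the trajectory. Uses the
#' compiled vector field; tiny solver-induced negative excursions are clipped
#' to zero in the returned states.
#'
#' @param p A [seagrass_params()] object.
#' @param cfg A [scenario_config()] object.
#' @return An object of class `seagrass_trajectory`: list with `times`
#'   (days), `states` (matrix with columns `Z`, `S`, `OM`, `L`), `params`,
#'   and `config`.
#' @examples
#' \donttest{
#' tr <- simulate_model(seagrass_params(), scenario_config(years = 20))
#' tail(as.data.frame(tr))
#' }
#' @export
simulate_model <- function(p = seagrass_params(), cfg = scenario_config()) {
  p <- as_seagrass_params(p)
  stopifnot(inherits(cfg, "scenario_config"))
  y0 <- cfg$initial_state
  if (is.null(y0)) y0 <- default_initial_state(p, cfg$mutualism)
  y0 <- model_state(Z = y0[["Z"]], S = y0[["S"]], OM = y0[["OM"]],
                    L = y0[["L"]])
  times <- seq(0, cfg$duration_days, by = cfg$output_step)
  if (times[length(times)] < cfg$duration_days)
    times <- c(times, cfg$duration_days)
  out <- deSolve::ode(y = y0, times = times, func = "seagrass_derivs",
                      parms = rhs_parms(p, cfg$mutualism),
                      dllname = "seagrassdyn", initfunc = "seagrass_initmod",
                      method = "lsoda", rtol = cfg$rtol, atol = cfg$atol,
                      maxsteps = 100000)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop("solver failed (istate = ", istate[1], ") near t = ",
         signif(max(out[, 1]), 6), " days")
  states <- pmax(unclass(out)[, c("Z", "S", "OM", "L"), drop = FALSE], 0)
  structure(list(times = out[, 1], states = states, params = p, config = cfg),
            class = "seagrass_trajectory")
}

#' @export
as.data.frame.seagrass_trajectory <- function(x, ...) {
  data.frame(t_days = x$times,
             Z = x$states[, "Z"], S = x$states[, "S"],
             OM = x$states[, "OM"], L = x$states[, "L"])
}

#' @export
print.seagrass_trajectory <- function(x, ...) {
  cat(sprintf("Seagrass model trajectory: %.1f years, %d output points, mutualism %s\n",
              max(x$times) / 365, length(x$times),
              if (x$config$mutualism) "on" else "off"))
  fin <- x$states[nrow(x$states), ]
  cat(sprintf("  final state: Z = %.4g shoots m-2, S = %.4g umol L-1, OM = %.4g %%, L = %.4g ind m-2\n",
              fin["Z"], fin["S"], fin["OM"], fin["L"]))
  invisible(x)
}

#' @export
plot.seagrass_trajectory <- function(x, vars = c("Z", "S", "OM", "L"), ...) {
  op <- graphics::par(mfrow = c(length(vars), 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  for (v in vars) {
    graphics::plot(x$times / 365, x$states[, v], type = "l",
                   xlab = "years", ylab = v, ...)
  }
  invisible(x)
}

#' Export a trajectory to CSV
#'
#' Writes the columns `t_days,Z,S,OM,L`.
#'
#' @param traj A `seagrass_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

# Interior local maxima/minima of a series; returns indices.
local_extrema <- function(z, maxima = TRUE) {
  d <- diff(z)
  s <- sign(d)
  # collapse flat segments so plateaus register once
  idx <- which(s != 0)
  if (length(idx) < 2) return(integer(0))
  turns <- which(diff(s[idx]) == if (maxima) -2 else 2)
  idx[turns] + 1L
}

#' Classify the post-transient dynamical regime of a trajectory
#'
#' Discards a transient window, then labels the seagrass dynamics as one of
#' `stable_equilibrium`, `damped_oscillation`, `limit_cycle`, or `collapsed`
#' from the relative amplitude of `Z` and the decay (or not) of successive
#' oscillation peaks:
#' * relative amplitude `a = (max - min) / max(mean, eps)` over the window;
#' * `collapsed` if the whole window stays below 1% of `Z_max`, or its mean
#'   is below 1% of `Z_max` with `a <= amplitude_tol`;
#' * `limit_cycle` if `a > amplitude_tol`, at least two significant interior
#'   peaks exist (topographic prominence above 5% of the window's `Z`
#'   range, which screens out solver-level wiggles during bare phases), and
#'   peak amplitudes do not decay (last/first prominence >= 0.9);
#' * `damped_oscillation` if `a > amplitude_tol` with decaying peaks (or an
#'   unfinished approach to a point);
#' * otherwise `stable_equilibrium`.
#'
#' @param traj A `seagrass_trajectory`.
#' @param transient_days Length of the discarded transient, days. Default:
#'   200 years or half the run, whichever is larger, capped so that at least
#'   a fifth of the run remains.
#' @param amplitude_tol Relative `Z` amplitude below which the window counts
#'   as constant.
#' @return An object of class `regime_label`: list with `regime`, and the
#'   post-transient `Z_mean`, `Z_min`, `Z_max`, plus `period_days` (`NA`
#'   unless `limit_cycle`).
#' @export
classify_regime <- function(traj, transient_days = NULL,
                            amplitude_tol = 1e-3) {
  stopifnot(inherits(traj, "seagrass_trajectory"))
  if (amplitude_tol <= 0) stop("amplitude_tol must be positive")
  if (any(!is.finite(traj$states))) stop("trajectory contains non-finite values")
  dur <- max(traj$times)
  if (is.null(transient_days)) {
    transient_days <- max(200 * 365, 0.5 * dur)
    if (transient_days >= 0.8 * dur) transient_days <- 0.5 * dur
  }
  if (transient_days >= dur)
    stop("trajectory (", signif(dur, 4), " d) not longer than the transient (",
         signif(transient_days, 4), " d)")
  keep <- traj$times > transient_days
  t <- traj$times[keep]
  z <- traj$states[keep, "Z"]
  zmean <- mean(z); zmin <- min(z); zmax <- max(z)
  a <- (zmax - zmin) / max(zmean, .Machine$double.eps)
  p_zmax <- traj$params$Z_max

  regime <- "stable_equilibrium"
  period <- NA_real_
  sigamp <- 0.05 * (zmax - zmin)
  pp <- peak_prominence(z)
  sig <- pp$prominence >= sigamp
  pk <- pp$index[sig]
  amp <- pp$prominence[sig]
  # merge peaks not separated by a real valley (slow-fast plateaus carry
  # equal-height micro-peaks that would otherwise each count as a cycle)
  if (length(pk) > 1) {
    keep <- 1L
    for (q in 2:length(pk)) {
      i <- pk[keep[length(keep)]]; j <- pk[q]
      if (min(z[i:j]) <= min(z[i], z[j]) - sigamp) keep <- c(keep, q)
    }
    pk <- pk[keep]; amp <- amp[keep]
  }
  if (length(pk) >= 4) {
    # peaks abutting the window edges can be truncated mid-cycle; drop them
    pk <- pk[-c(1, length(pk))]
    amp <- amp[-c(1, length(amp))]
  }
  if (zmax < 0.01 * p_zmax || (zmean < 0.01 * p_zmax && a <= amplitude_tol)) {
    regime <- "collapsed"
  } else if (a > amplitude_tol) {
    k <- length(amp)
    decay <- if (k >= 6) {
      third <- floor(k / 3)
      stats::median(amp[seq.int(k - third + 1L, k)]) /
        stats::median(amp[seq_len(third)])
    } else if (k >= 2) {
      amp[k] / amp[1]
    } else {
      0
    }
    if (decay >= 0.9) {
      regime <- "limit_cycle"
      period <- mean(diff(t[pk]))
    } else {
      regime <- "damped_oscillation"
    }
  }
  structure(list(regime = regime, Z_mean = zmean, Z_min = zmin, Z_max = zmax,
                 period_days = period, amplitude = a),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("Regime: %s  (post-transient Z mean %.4g, range [%.4g, %.4g]",
              x$regime, x$Z_mean, x$Z_min, x$Z_max))
  if (!is.na(x$period_days)) cat(sprintf(", period %.3g yr", x$period_days / 365))
  cat(")\n")
  invisible(x)
}
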