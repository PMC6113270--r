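# Regime at one parameter setting: integrate settle + window years and
# classify the window. Used by the scans and the bisection search.
regime_at <- function(p, mutualism = TRUE, settle_years = 300,
                      window_years = 300, init = NULL, output_step = 14,
                      amplitude_tol = 1e-3) {
  cfg <- scenario_config(mutualism = mutualism,
                         years = settle_years + window_years,
                         initial_state = init, output_step = output_step)
  traj <- simulate_model(p, cfg)
  lab <- classify_regime(traj, transient_days = settle_years * 365,
                         amplitude_tol = amplitude_tol)
  lab$final_state <- traj$states[nrow(traj$states), ]
  lab
}

#' Bifurcation scan of the background mortality rate
#'
#' Steps the natural mortality `m_n` (the desiccation-stress proxy) across a
#' range, integrating to post-transient statistics at every value and
#' labelling the regime. By default each step is warm-started from the final
#' state of the previous one (continuation), which is how forward and
#' backward sweeps can expose alternative equilibria; `continuation = FALSE`
#' restarts every step from the default sparse-bed initial state.
#'
#' @param p A [seagrass_params()] object.
#' @param lo,hi Scan range of `m_n`, day^-1.
#' @param n_steps Number of scanned values (inclusive of both ends).
#' @param direction `"forward"` (increasing `m_n`) or `"backward"`.
#' @param mutualism Logical, passed to the integrator.
#' @param continuation Warm-start each step from the previous final state?
#' @param settle_years,window_years Transient discarded and window
#'   classified at each step, years.
#' @param amplitude_tol Relative amplitude tolerance of [classify_regime()].
#' @return An object of class `bifurcation_result`: a data frame with one
#'   row per scanned value (`value`, `regime`, `Z_min`, `Z_mean`, `Z_max`,
#'   `period_days`) and attributes `parameter`, `direction`.
#' @examples
#' \donttest{
#' sc <- scan_mortality(n_steps = 20, lo = 0.01, hi = 0.05,
#'                      settle_years = 300, window_years = 200)
#' subset(sc, regime == "limit_cycle")[1, "value"]
#' }
#' @export
scan_mortality <- function(p = seagrass_params(), lo = 0, hi = 0.35,
                           n_steps = 150, direction = c("forward", "backward"),
                           mutualism = TRUE, continuation = TRUE,
                           settle_years = 300, window_years = 300,
                           amplitude_tol = 1e-3) {
  p <- as_seagrass_params(p)
  direction <- match.arg(direction)
  if (!(lo >= 0 && lo < hi)) stop("need 0 <= lo < hi")
  if (n_steps < 2) stop("n_steps must be at least 2")
  values <- seq(lo, hi, length.out = n_steps)
  if (direction == "backward") values <- rev(values)
  init <- NULL
  rows <- vector("list", n_steps)
  for (i in seq_along(values)) {
    pi <- set_param(p, "m_n", values[i])
    lab <- tryCatch(
      regime_at(pi, mutualism = mutualism, settle_years = settle_years,
                window_years = window_years, init = init,
                amplitude_tol = amplitude_tol),
      error = function(e) stop("scan step ", i, " (m_n = ",
                               signif(values[i], 6), ") failed: ",
                               conditionMessage(e)))
    if (continuation) init <- pmax(lab$final_state, 0)
    rows[[i]] <- data.frame(value = values[i], regime = lab$regime,
                            Z_min = lab$Z_min, Z_mean = lab$Z_mean,
                            Z_max = lab$Z_max, period_days = lab$period_days)
  }
  res <- do.call(rbind, rows)
  attr(res, "parameter") <- "m_n"
  attr(res, "direction") <- direction
  attr(res, "continuation") <- continuation
  class(res) <- c("bifurcation_result", "data.frame")
  res
}

#' @export
print.bifurcation_result <- function(x, ...) {
  cat(sprintf("Bifurcation scan of %s (%s%s): %d values in [%g, %g]\n",
              attr(x, "parameter"), attr(x, "direction"),
              if (isTRUE(attr(x, "continuation"))) ", continuation" else "",
              nrow(x), min(x$value), max(x$value)))
  tab <- table(x$regime)
  cat("  regimes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cyc <- x$value[x$regime == "limit_cycle"]
  if (length(cyc))
    cat(sprintf("  first limit cycle at %s = %.5g\n",
                attr(x, "parameter"), min(cyc)))
  invisible(x)
}

#' @export
plot.bifurcation_result <- function(x, ...) {
  graphics::plot(x$value, x$Z_mean, type = "l", ylim = range(x$Z_min, x$Z_max),
                 xlab = attr(x, "parameter"), ylab = "post-transient Z", ...)
  graphics::lines(x$value, x$Z_min, lty = 2)
  graphics::lines(x$value, x$Z_max, lty = 2)
  invisible(x)
}

is_cycling <- function(p, name, value, mutualism, settle_years, window_years) {
  pv <- tryCatch(set_param(p, name, value), error = function(e) NULL)
  if (is.null(pv)) return(NA)
  lab <- tryCatch(
    regime_at(pv, mutualism = mutualism, settle_years = settle_years,
              window_years = window_years),
    error = function(e) NULL)
  if (is.null(lab)) return(NA)
  lab$regime == "limit_cycle"
}

#' Locate the onset of sustained cycles along one parameter
#'
#' Searches an interval of a single model parameter (all others held at
#' their values in `p`, mutualism on unless disabled) for the boundary
#' between non-cycling and limit-cycle dynamics. A coarse grid first maps
#' where the cycling label changes; the change bracket nearest the
#' parameter's current (default) value is then refined by bisection until
#' it is narrower than `tol`, and the bracket midpoint is returned. When the
#' grid shows several separate transitions all brackets are reported (in the
#' `brackets` element), and the returned threshold is the one nearest the
#' default. Long transients near onset are handled by a generous settle
#' window (default 500 years).
#'
#' @param p A [seagrass_params()] object.
#' @param name Parameter name.
#' @param interval Numeric length-2 search interval (must contain the
#'   parameter's value in `p`, or touch it at one end).
#' @param tol Absolute bisection tolerance on the parameter.
#' @param mutualism Logical.
#' @param settle_years,window_years Per-evaluation transient and window.
#' @param coarse_n Size of the initial mapping grid.
#' @param log_scale Place the coarse grid uniformly in log space (used for
#'   parameters spanning decades)?
#' @return An object of class `cycle_threshold`: list with `threshold` (or
#'   `NA` if the regime never changes in the interval), `parameter`,
#'   `default`, `brackets` (matrix of all change brackets after refinement
#'   of the nearest one), and `cycling_at_default`.
#' @examples
#' \donttest{
#' find_cycle_threshold(interval = c(0.01, 0.05), tol = 1e-4)  # ~0.0235
#' }
#' @export
find_cycle_threshold <- function(p = seagrass_params(), name = "m_n",
                                 interval, tol = 1e-4, mutualism = TRUE,
                                 settle_years = 500, window_years = 300,
                                 coarse_n = 16, log_scale = FALSE) {
  p <- as_seagrass_params(p)
  if (!name %in% param_names()) stop("unknown parameter name: ", name)
  if (length(interval) != 2 || diff(interval) < 0)
    stop("interval must be c(lo, hi) with lo <= hi")
  d <- p[[name]]
  lo <- interval[1]; hi <- interval[2]
  # reference point for "nearest transition": the default, clamped into the
  # searched interval when it lies outside
  dref <- min(max(d, lo), hi)
  if (lo == hi) {
    return(structure(list(threshold = NA_real_, parameter = name, default = d,
                          brackets = NULL, cycling_at_default = NA),
                     class = "cycle_threshold"))
  }
  grid <- if (log_scale) {
    exp(seq(log(max(lo, 1e-12 * max(hi, 1))), log(hi), length.out = coarse_n))
  } else {
    seq(lo, hi, length.out = coarse_n)
  }
  grid <- sort(unique(c(grid, dref)))
  cyc <- vapply(grid, function(v)
    is_cycling(p, name, v, mutualism, settle_years, window_years),
    logical(1))
  ok <- !is.na(cyc)
  grid <- grid[ok]; cyc <- cyc[ok]
  if (length(grid) < 2 || length(unique(cyc)) == 1) {
    return(structure(list(threshold = NA_real_, parameter = name, default = d,
                          brackets = NULL,
                          cycling_at_default = cyc[which.min(abs(grid - dref))]),
                     class = "cycle_threshold"))
  }
  change <- which(diff(cyc) != 0)
  brackets <- cbind(lo = grid[change], hi = grid[change + 1])
  # refine the bracket whose nearest edge is closest to the default
  dist <- pmin(abs(brackets[, 1] - dref), abs(brackets[, 2] - dref))
  k <- which.min(dist)
  blo <- brackets[k, 1]; bhi <- brackets[k, 2]
  clo <- cyc[change[k]]
  while (bhi - blo > tol) {
    mid <- if (log_scale) sqrt(blo * bhi) else (blo + bhi) / 2
    cm <- is_cycling(p, name, mid, mutualism, settle_years, window_years)
    if (is.na(cm)) break
    if (cm == clo) blo <- mid else bhi <- mid
  }
  brackets[k, ] <- c(blo, bhi)
  structure(list(threshold = (blo + bhi) / 2, parameter = name, default = d,
                 brackets = brackets,
                 cycling_at_default = cyc[which.min(abs(grid - dref))]),
            class = "cycle_threshold")
}

#' @export
print.cycle_threshold <- function(x, ...) {
  if (is.na(x$threshold)) {
    cat(sprintf("No cycle-onset threshold for %s in the searched interval\n",
                x$parameter))
  } else {
    cat(sprintf("Cycle onset: %s = %.6g (default %.6g, %+.1f%%)\n",
                x$parameter, x$threshold, x$default,
                100 * (x$threshold - x$default) / x$default))
    if (!is.null(x$brackets) && nrow(x$brackets) > 1)
      cat("  note:", nrow(x$brackets), "separate regime transitions in the interval\n")
  }
  invisible(x)
}

#' Per-parameter sensitivity of the cycle onset
#'
#' For each named parameter at otherwise default settings (mutualism on),
#' searches a multiplicative interval around its default for the nearest
#' value at which sustained cycles appear (or disappear, if the default
#' already cycles), and expresses that threshold as a percent change from
#' the default. The multiplicative search and log-spaced mapping grid
#' accommodate parameters spanning many orders of magnitude. Parameters for
#' which no regime change occurs anywhere in the searched range get an `NA`
#' threshold.
#'
#' @param p A [seagrass_params()] object.
#' @param parameters Character vector of parameter names (default: all 14).
#' @param range Multiplicative search range `c(lo, hi)` applied to each
#'   default, i.e. the interval is `default * range`.
#' @param tol_rel Relative bisection tolerance (absolute tolerance is
#'   `tol_rel * default` per parameter).
#' @param settle_years,window_years Per-evaluation transient and window.
#' @param coarse_n Mapping-grid size per parameter.
#' @return An object of class `sensitivity_result`: a data frame with one
#'   row per parameter (`parameter`, `default`, `threshold`,
#'   `percent_change`), sorted by `percent_change` ascending, `NA` last.
#' @examples
#' \donttest{
#' sens <- sensitivity_analysis(parameters = c("e_s", "C_om"))
#' min(sens$percent_change, na.rm = TRUE)
#' }
#' @export
sensitivity_analysis <- function(p = seagrass_params(),
                                 parameters = param_names(),
                                 range = c(0.01, 100), tol_rel = 0.01,
                                 settle_years = 400, window_years = 300,
                                 coarse_n = 16) {
  p <- as_seagrass_params(p)
  bad <- setdiff(parameters, param_names())
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  rows <- lapply(parameters, function(nm) {
    d <- p[[nm]]
    if (d <= 0)
      return(data.frame(parameter = nm, default = d, threshold = NA_real_,
                        percent_change = NA_real_))
    th <- find_cycle_threshold(p, nm, interval = d * range,
                               tol = tol_rel * d,
                               settle_years = settle_years,
                               window_years = window_years,
                               coarse_n = coarse_n, log_scale = TRUE)
    data.frame(parameter = nm, default = d, threshold = th$threshold,
               percent_change = 100 * abs(th$threshold - d) / d)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$percent_change, na.last = TRUE), ]
  rownames(res) <- NULL
  class(res) <- c("sensitivity_result", "data.frame")
  res
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("Cycle-onset sensitivity (percent change from default):\n")
  print.data.frame(x, digits = 4)
  m <- suppressWarnings(min(x$percent_change, na.rm = TRUE))
  if (is.finite(m))
    cat(sprintf("  minimum change to alter the default dynamics: %.3g%%\n", m))
  invisible(x)
}
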