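#' Stochastic ensemble configuration
#'
#' Protocol for the ensemble runs that feed the potential analysis: a grid
#' of background-mortality values (the stress gradient), many replicate
#' integrations per grid value with the carrying capacity perturbed once per
#' replicate, a burn-in, and yearly state sampling. The defaults are the
#' full study protocol: 61 mortality steps of 0.0025 day^-1 over 0-0.15,
#' 625 replicates, 200 burn-in years, 50 sampled years, and a relative
#' carrying-capacity standard deviation of 0.15 (so that the high attractor
#' at `Z_max = 8000` carries a spread of 1200 shoots m^-2).
#'
#' @param mn_values Mortality grid, day^-1 (strictly increasing).
#' @param replicates Replicate runs per grid value.
#' @param burn_years Discarded stabilisation period, years.
#' @param sample_years Years sampled (state recorded at each year's end).
#' @param sigma Relative standard deviation of the per-replicate carrying
#'   capacity multiplier `1 + e`, `e ~ Normal(0, sigma^2)` truncated to keep
#'   the multiplier positive.
#' @param seed Optional integer seed; same seed, same samples.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(mn_values = seq(0, 0.15, by = 0.0025),
                            replicates = 625, burn_years = 200,
                            sample_years = 50, sigma = 0.15, seed = NULL) {
  if (length(mn_values) < 1 || any(diff(mn_values) <= 0) || any(mn_values < 0))
    stop("mn_values must be a non-negative strictly increasing grid")
  if (replicates < 1) stop("need at least one replicate")
  if (sigma < 0) stop("sigma must be non-negative")
  if (burn_years < 0 || sample_years < 1) stop("invalid year counts")
  structure(list(mn_values = mn_values, replicates = as.integer(replicates),
                 burn_years = burn_years, sample_years = sample_years,
                 sigma = sigma, seed = seed),
            class = "ensemble_config")
}

#' Run the stochastic ensemble over the mortality gradient
#'
#' For every mortality value and replicate, draws a perturbed carrying
#' capacity `Z_max * (1 + e)` (one draw per replicate, fixed for the whole
#' run), integrates the mutualism model through the burn-in, and records the
#' shoot density at the end of each sampled year. All multipliers are drawn
#' up front from the seeded RNG in a fixed order, so results do not depend
#' on loop scheduling. Replicates whose integration fails are skipped and
#' counted; more than 1% failures is an error.
#'
#' @param p A [seagrass_params()] object.
#' @param cfg An [ensemble_config()] object.
#' @return An object of class `ensemble_samples`: list with `classes` (the
#'   mortality grid), `samples` (one numeric vector of pooled yearly shoot
#'   densities per class), `failures`, `provenance = "model"`, and the
#'   configuration.
#' @examples
#' \donttest{
#' cfg <- ensemble_config(mn_values = 0.007, replicates = 50, seed = 1)
#' es <- run_ensemble(cfg = cfg)
#' c(mean(es$samples[[1]]), sd(es$samples[[1]]))  # ~7840, ~1170
#' }
#' @export
run_ensemble <- function(p = seagrass_params(), cfg = ensemble_config()) {
  p <- as_seagrass_params(p)
  stopifnot(inherits(cfg, "ensemble_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_cl <- length(cfg$mn_values)
  # one multiplier per replicate per class, drawn up front in fixed order
  mult <- matrix(1 + stats::rnorm(cfg$replicates * n_cl, 0, cfg$sigma),
                 nrow = cfg$replicates, ncol = n_cl)
  while (any(bad <- mult <= 0))
    mult[bad] <- 1 + stats::rnorm(sum(bad), 0, cfg$sigma)
  total_years <- cfg$burn_years + cfg$sample_years
  keep <- cfg$burn_years + seq_len(cfg$sample_years)  # year indices sampled
  failures <- 0L
  samples <- vector("list", n_cl)
  for (j in seq_len(n_cl)) {
    pj <- set_param(p, "m_n", cfg$mn_values[j])
    out <- vector("list", cfg$replicates)
    for (i in seq_len(cfg$replicates)) {
      pi <- set_param(pj, "Z_max", pj$Z_max * mult[i, j])
      traj <- tryCatch(
        simulate_model(pi, scenario_config(mutualism = TRUE,
                                           years = total_years,
                                           output_step = 365)),
        error = function(e) NULL)
      if (is.null(traj)) { failures <- failures + 1L; next }
      # row 1 is t = 0; year k ends at row k + 1
      out[[i]] <- traj$states[keep + 1L, "Z"]
    }
    samples[[j]] <- unlist(out)
    if (!length(samples[[j]]))
      stop("all replicates failed at m_n = ", cfg$mn_values[j])
  }
  if (failures > 0.01 * cfg$replicates * n_cl)
    stop("more than 1% of ensemble replicates failed (", failures, ")")
  names(samples) <- formatC(cfg$mn_values, format = "g")
  structure(list(classes = cfg$mn_values, samples = samples,
                 failures = failures, provenance = "model", config = cfg),
            class = c("ensemble_samples", "stress_classed_samples"))
}

#' @export
print.ensemble_samples <- function(x, ...) {
  cat(sprintf("Stochastic ensemble: %d mortality class(es), %d replicates x %d years (sigma = %g)\n",
              length(x$classes), x$config$replicates, x$config$sample_years,
              x$config$sigma))
  if (x$failures) cat("  skipped replicates:", x$failures, "\n")
  for (j in seq_along(x$classes))
    cat(sprintf("  m_n = %-8g n = %-6d Z mean %.4g sd %.4g\n",
                x$classes[j], length(x$samples[[j]]),
                mean(x$samples[[j]]), stats::sd(x$samples[[j]])))
  invisible(x)
}

#' @export
as.data.frame.ensemble_samples <- function(x, ...) {
  reps <- x$config$replicates
  yrs <- x$config$sample_years
  do.call(rbind, lapply(seq_along(x$classes), function(j) {
    n <- length(x$samples[[j]])
    k <- seq_len(n) - 1L
    data.frame(class_value = x$classes[j],
               replicate = k %/% yrs + 1L,
               year = k %% yrs + 1L,
               Z = x$samples[[j]])
  }))
}

#' Bundle scalar observations by stress class
#'
#' Generic container used by [potential_landscape()]: a list of numeric
#' sample vectors, one per ordered stress-class value (a mortality rate or
#' an elevation-class midpoint).
#'
#' @param classes Numeric vector of class values, strictly increasing.
#' @param samples List of numeric vectors, one per class, all non-empty and
#'   finite.
#' @param provenance Character tag, e.g. `"model"` or `"synthetic_field"`.
#' @return An object of class `stress_classed_samples`.
#' @export
stress_classed_samples <- function(classes, samples, provenance = "model") {
  if (length(classes) != length(samples))
    stop("classes and samples must have equal length")
  if (any(diff(classes) <= 0)) stop("classes must be strictly increasing")
  ok <- vapply(samples, function(s) length(s) > 0 && all(is.finite(s)),
               logical(1))
  if (!all(ok))
    stop("empty or non-finite sample vector(s) in class(es): ",
         paste(classes[!ok], collapse = ", "))
  structure(list(classes = classes, samples = samples,
                 provenance = provenance),
            class = "stress_classed_samples")
}
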