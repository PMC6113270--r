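#' Configuration of the synthetic NDVI-by-elevation generator
#'
#' Describes a synthetic stand-in for an intertidal remote-sensing dataset:
#' annual NDVI maps over an elevation gradient, with pixels allocated to
#' fixed-width elevation classes and per-class NDVI distributions ranging
#' from unimodal vegetated (low elevation, little desiccation stress)
#' through bimodal (intermediate) to unimodal bare (high elevation). The
#' default geometry matches the study structure the package emulates:
#' 17,672 pixels per annual map, four years, nine 0.1-m classes spanning
#' -0.6 to +0.3 m relative to mean water level.
#'
#' Each class's NDVI is a two-component Gaussian mixture (truncated to
#' `[-1, 1]`): a vegetated state and a bare state, mixed with a
#' high-state weight that decreases monotonically with elevation — 1 below
#' `bimodal_range[1]`, 0 above `bimodal_range[2]`, linear in between.
#'
#' @param years Year labels (cosmetic in the default mixture mode).
#' @param pixels_per_year Pixels per annual map.
#' @param elev_range Elevation range `c(lo, hi)`, metres relative to mean
#'   water level.
#' @param class_width Elevation class width, metres; must divide the range.
#' @param high_mean,high_sd Vegetated-state NDVI mean and SD.
#' @param low_mean,low_sd Bare-state NDVI mean and SD.
#' @param bimodal_range Elevation band over which the high-state weight
#'   ramps from 1 to 0.
#' @param mode `"mixture"` (default, distributional) or `"mechanistic"`
#'   (NDVI derived from simulated shoot densities; see
#'   [generate_field_dataset()]).
#' @param seed Optional integer seed.
#' @return An object of class `field_config`.
#' @export
field_config <- function(years = c(2007, 2009, 2011, 2013),
                         pixels_per_year = 17672,
                         elev_range = c(-0.6, 0.3),
                         class_width = 0.1,
                         high_mean = 0.6, high_sd = 0.08,
                         low_mean = 0.05, low_sd = 0.05,
                         bimodal_range = c(-0.3, 0),
                         mode = c("mixture", "mechanistic"),
                         seed = NULL) {
  mode <- match.arg(mode)
  if (length(elev_range) != 2 || diff(elev_range) <= 0)
    stop("elev_range must be c(lo, hi) with lo < hi")
  n_classes <- diff(elev_range) / class_width
  if (abs(n_classes - round(n_classes)) > 1e-8)
    stop("class_width must divide the elevation range")
  if (abs(high_mean) > 1 || abs(low_mean) > 1)
    stop("NDVI means must lie in [-1, 1]")
  if (high_sd <= 0 || low_sd <= 0) stop("state SDs must be positive")
  if (length(bimodal_range) != 2 || diff(bimodal_range) <= 0)
    stop("bimodal_range must be c(lo, hi) with lo < hi")
  structure(list(years = years, pixels_per_year = as.integer(pixels_per_year),
                 elev_range = elev_range, class_width = class_width,
                 n_classes = as.integer(round(n_classes)),
                 high_mean = high_mean, high_sd = high_sd,
                 low_mean = low_mean, low_sd = low_sd,
                 bimodal_range = bimodal_range, mode = mode, seed = seed),
            class = "field_config")
}

# High-state (vegetated) mixing weight at a given elevation: monotone
# non-increasing ramp from 1 to 0 across the bimodal band.
high_state_weight <- function(elevation, cfg) {
  lo <- cfg$bimodal_range[1]; hi <- cfg$bimodal_range[2]
  pmin(1, pmax(0, (hi - elevation) / (hi - lo)))
}

#' Elevation class midpoints and expected modality of a field configuration
#'
#' Returns, per elevation class, the midpoint, the vegetated-state mixing
#' weight there, and the number of modes the generator is configured to
#' produce (2 where the weight is strictly between 0 and 1, else 1). Used
#' for parameter-recovery checks of the potential analysis.
#'
#' @param cfg A [field_config()] object.
#' @param eps Weights within `eps` of 0 or 1 count as unimodal.
#' @return Data frame with columns `class`, `weight`, `modes`.
#' @export
field_class_modality <- function(cfg, eps = 1e-9) {
  stopifnot(inherits(cfg, "field_config"))
  mids <- cfg$elev_range[1] + (seq_len(cfg$n_classes) - 0.5) * cfg$class_width
  w <- high_state_weight(mids, cfg)
  data.frame(class = mids, weight = w,
             modes = ifelse(w > eps & w < 1 - eps, 2L, 1L))
}

rtruncnorm_ndvi <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < -1 | x > 1))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic NDVI-by-elevation dataset
#'
#' Draws pixel elevations uniformly over the configured range, assigns each
#' pixel to its elevation class, and samples NDVI per pixel. In the default
#' `"mixture"` mode NDVI comes from the class's two-component truncated
#' Gaussian mixture, with years as exchangeable repeated draws. In
#' `"mechanistic"` mode each class midpoint is mapped to a background
#' mortality via [link_elevation_to_mortality()], a small stochastic
#' ensemble of the mutualism model supplies shoot densities, and NDVI is a
#' saturating function of shoot density plus observation noise — slower, but
#' dynamically coupled to the model arm.
#'
#' @param cfg A [field_config()] object.
#' @param p Model parameters (mechanistic mode only).
#' @param replicates Ensemble replicates per class (mechanistic mode only).
#' @return An object of class `field_dataset`: a data frame with columns
#'   `pixel_id`, `year`, `elevation_m`, `class` (class midpoint, metres),
#'   `ndvi`, with the generating configuration in `attr(, "config")`.
#' @examples
#' fd <- generate_field_dataset(field_config(pixels_per_year = 500, seed = 1))
#' nrow(fd)  # 4 years x 500 pixels
#' @export
generate_field_dataset <- function(cfg = field_config(), p = seagrass_params(),
                                   replicates = 25) {
  stopifnot(inherits(cfg, "field_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  mids <- cfg$elev_range[1] + (seq_len(cfg$n_classes) - 0.5) * cfg$class_width
  n_yr <- length(cfg$years)
  npx <- cfg$pixels_per_year

  mech_pools <- NULL
  if (cfg$mode == "mechanistic") {
    mn <- link_elevation_to_mortality(mids)
    mech_pools <- lapply(mn, function(m) {
      es <- run_ensemble(p, ensemble_config(mn_values = m,
                                            replicates = replicates,
                                            burn_years = 200,
                                            sample_years = n_yr * 5,
                                            sigma = 0.15))
      es$samples[[1]]
    })
  }

  out <- vector("list", n_yr)
  for (k in seq_len(n_yr)) {
    elev <- stats::runif(npx, cfg$elev_range[1], cfg$elev_range[2])
    cls_i <- pmin(cfg$n_classes,
                  1L + floor((elev - cfg$elev_range[1]) / cfg$class_width))
    ndvi <- numeric(npx)
    for (j in seq_len(cfg$n_classes)) {
      in_j <- which(cls_i == j)
      if (!length(in_j)) next
      if (cfg$mode == "mixture") {
        w <- high_state_weight(mids[j], cfg)
        hi <- stats::runif(length(in_j)) < w
        ndvi[in_j[hi]] <- rtruncnorm_ndvi(sum(hi), cfg$high_mean, cfg$high_sd)
        ndvi[in_j[!hi]] <- rtruncnorm_ndvi(sum(!hi), cfg$low_mean, cfg$low_sd)
      } else {
        z <- sample(mech_pools[[j]], length(in_j), replace = TRUE)
        v <- 0.8 * z / (z + 0.2 * p$Z_max) + stats::rnorm(length(in_j), 0, 0.03)
        ndvi[in_j] <- pmin(1, pmax(-1, v))
      }
    }
    out[[k]] <- data.frame(pixel_id = seq_len(npx), year = cfg$years[k],
                           elevation_m = elev, class = mids[cls_i],
                           ndvi = ndvi)
  }
  res <- do.call(rbind, out)
  attr(res, "config") <- cfg
  class(res) <- c("field_dataset", "data.frame")
  res
}

#' Group a field dataset into stress-classed samples
#'
#' Pools all years and groups NDVI by elevation class, ready for
#' [potential_landscape()].
#'
#' @param dataset A `field_dataset` (or any data frame with `class` and
#'   `ndvi` columns).
#' @return A `stress_classed_samples` object with provenance
#'   `"synthetic_field"`.
#' @export
field_to_classes <- function(dataset) {
  cls <- sort(unique(dataset$class))
  samples <- lapply(cls, function(cv) dataset$ndvi[dataset$class == cv])
  stress_classed_samples(cls, samples, provenance = "synthetic_field")
}

#' Map elevation to background mortality
#'
#' Desiccation stress increases with elevation (longer low-tide exposure);
#' this maps elevation (m relative to mean water level) to the model's
#' natural mortality rate `m_n` by monotone piecewise-linear interpolation.
#' The default map sends -0.6 m to the calibrated default mortality
#' (0.007 day^-1) and +0.3 m to 0.15 day^-1, the top of the ensemble's
#' stress gradient. Elevations outside the mapped range take the endpoint
#' values.
#'
#' @param elevation Elevation(s), metres relative to mean water level.
#' @param map List with numeric vectors `elevation` and `m_n` of equal
#'   length (>= 2); `m_n` must be non-decreasing in `elevation`.
#' @return Mortality rate(s), day^-1.
#' @examples
#' link_elevation_to_mortality(c(-0.6, 0.3))  # c(0.007, 0.15)
#' @export
link_elevation_to_mortality <- function(elevation,
                                        map = list(elevation = c(-0.6, 0.3),
                                                   m_n = c(0.007, 0.15))) {
  if (length(map$elevation) != length(map$m_n) || length(map$m_n) < 2)
    stop("map must give matching elevation and m_n vectors (length >= 2)")
  if (any(diff(map$elevation) <= 0))
    stop("map elevations must be strictly increasing")
  if (any(diff(map$m_n) < 0))
    stop("mapping must be monotone non-decreasing in elevation")
  stats::approx(map$elevation, map$m_n, xout = elevation, rule = 2)$y
}
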