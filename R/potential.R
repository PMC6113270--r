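#' Normal-reference bin width / kernel bandwidth
#'
#' The classic normal-reference rule `h = 1.06 * s * n^(-1/5)` (sample
#' standard deviation `s`, sample size `n`), used both as the histogram bin
#' width for reporting and as the Gaussian kernel bandwidth of
#' [estimate_density()].
#'
#' @param values Numeric sample (at least 2 values, positive spread).
#' @return The width `h`, in the units of `values`.
#' @examples
#' bin_width(rnorm(1000))
#' @export
bin_width <- function(values) {
  if (any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  if (n < 2) stop("degenerate sample: need at least 2 observations")
  s <- stats::sd(values)
  if (s == 0) stop("degenerate sample: zero standard deviation")
  1.06 * s * n^(-1 / 5)
}

#' Gaussian kernel density on an explicit grid
#'
#' Evaluates the Gaussian kernel density estimate
#' `Pd(x) = (1 / (n h)) * sum_i phi((x - z_i) / h)` exactly at each grid
#' point (direct kernel sum, no binning approximation), so that the result
#' is reproducible to machine precision and integrates to ~1 over a grid
#' spanning the sample.
#'
#' @param values Numeric sample (non-empty, finite).
#' @param grid Strictly increasing evaluation points.
#' @param h Kernel bandwidth (standard deviation of the Gaussian kernel),
#'   positive; default from [bin_width()].
#' @return Numeric vector of densities, one per grid point.
#' @export
estimate_density <- function(values, grid, h = bin_width(values)) {
  if (length(values) == 0) stop("empty sample")
  if (any(!is.finite(values)) || any(!is.finite(grid)))
    stop("values and grid must be finite")
  if (h <= 0) stop("bandwidth h must be positive")
  if (length(grid) > 1 && any(diff(grid) <= 0))
    stop("grid must be strictly increasing")
  n <- length(values)
  # chunk the grid to bound the n x m kernel matrix at ~8e6 doubles
  m <- length(grid)
  chunk <- max(1L, floor(8e6 / n))
  out <- numeric(m)
  for (i0 in seq(1L, m, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, m)
    K <- outer(values, grid[i0:i1], function(z, x) stats::dnorm((x - z) / h))
    out[i0:i1] <- colSums(K) / (n * h)
  }
  out
}

# Prominence of each interior local maximum of y: height above the higher
# of the two deepest valleys separating it from taller peaks (or the grid
# ends). Standard topographic-prominence definition on a 1-d series.
peak_prominence <- function(y) {
  idx <- local_extrema(y, maxima = TRUE)
  if (!length(idx)) return(list(index = integer(0), prominence = numeric(0)))
  prom <- vapply(idx, function(i) {
    left <- y[seq_len(i)]
    right <- y[i:length(y)]
    higher_l <- which(left > y[i])
    higher_r <- which(right > y[i])
    key_l <- if (length(higher_l)) min(left[max(higher_l):i]) else min(left)
    key_r <- if (length(higher_r)) min(right[1:min(higher_r)]) else min(right)
    y[i] - max(key_l, key_r)
  }, numeric(1))
  list(index = idx, prominence = prom)
}

#' Identify attractors and repellors in a density estimate
#'
#' Attractors are the local maxima of the probability density `Pd` whose
#' topographic prominence exceeds (i) a fraction of the global maximum and
#' (ii) a fraction of the peak's own height; repellors are the minima of
#' `Pd` between each adjacent attractor pair. Because `U = -log(Pd)` is a
#' monotone transform, these are identically the local minima and maxima of
#' the potential.
#'
#' The second, scale-free criterion is what suppresses sampling-noise
#' doublets: distinct basins of attraction are separated by rarely visited
#' states, so a genuine attractor's peak stands nearly full-height above its
#' valleys (relative prominence near 1), whereas finite-sample wiggles on
#' the flank of one basin rise only a few percent above theirs. Peaks whose
#' relative prominence falls below `min_rel_prominence` are treated as
#' unresolved structure of the surrounding basin.
#'
#' @param Pd Non-negative density values on a grid (at least 3 points).
#' @param grid The corresponding grid (defaults to indices).
#' @param prominence Required prominence as a fraction of `max(Pd)`.
#' @param min_rel_prominence Required prominence as a fraction of the
#'   peak's own height.
#' @return List with `attractors` and `repellors`: grid positions, plus
#'   `attractor_index`/`repellor_index` into the grid.
#' @examples
#' g <- seq(-4, 12, length.out = 512)
#' pd <- 0.5 * dnorm(g, 0) + 0.5 * dnorm(g, 8)
#' find_attractors(pd, g)$attractors  # ~c(0, 8)
#' @export
find_attractors <- function(Pd, grid = seq_along(Pd), prominence = 0.05,
                            min_rel_prominence = 0.5) {
  if (length(Pd) < 3) stop("need at least 3 grid points")
  if (any(!is.finite(Pd)) || any(Pd < 0)) stop("Pd must be finite and >= 0")
  if (length(grid) != length(Pd)) stop("grid and Pd lengths differ")
  pk <- peak_prominence(Pd)
  keep <- pk$prominence >= prominence * max(Pd) &
    pk$prominence >= min_rel_prominence * Pd[pk$index]
  ai <- pk$index[keep]
  ri <- integer(0)
  if (length(ai) > 1) {
    ri <- vapply(seq_len(length(ai) - 1), function(k) {
      seg <- ai[k]:ai[k + 1]
      seg[which.min(Pd[seg])]
    }, integer(1))
  }
  list(attractors = grid[ai], repellors = grid[ri],
       attractor_index = ai, repellor_index = ri)
}

#' Potential analysis of stress-classed samples
#'
#' For every stress class: compute the normal-reference width `h`
#' ([bin_width()]), estimate the Gaussian kernel density `Pd` on a regular
#' 512-point grid spanning `[min - 3h, max + 3h]`, form the potential
#' `U = -log(Pd)` (with a floor `Pd >= 1e-12` so `U` stays finite; attractor
#' logic operates on `Pd`, so the floor never changes results), and identify
#' attractors and repellors ([find_attractors()]). Classes whose sample is
#' degenerate (fewer than 2 values or zero spread) are flagged and skipped;
#' the rest are processed. Samples tagged as NDVI are clamped to `[-1, 1]`.
#'
#' @param samples A `stress_classed_samples` object (e.g. from
#'   [run_ensemble()] or [field_to_classes()]), or a single numeric vector
#'   (treated as one class).
#' @param prominence Peak-prominence threshold, fraction of the class's
#'   maximum density.
#' @param min_rel_prominence Scale-free prominence threshold, fraction of
#'   each peak's own height (see [find_attractors()]).
#' @param grid_n Grid resolution per class.
#' @param ndvi Clamp observations to `[-1, 1]` before analysis?
#' @return An object of class `potential_landscape`: list with `classes`
#'   and, per class, `h`, `grid`, `Pd`, `U`, `attractors`, `repellors`,
#'   `n`, and `degenerate` flag.
#' @export
potential_landscape <- function(samples, prominence = 0.05,
                                min_rel_prominence = 0.5, grid_n = 512,
                                ndvi = FALSE) {
  if (is.numeric(samples))
    samples <- stress_classed_samples(0, list(samples), provenance = "adhoc")
  stopifnot(inherits(samples, "stress_classed_samples"))
  per_class <- lapply(seq_along(samples$classes), function(j) {
    v <- samples$samples[[j]]
    if (ndvi) v <- pmin(1, pmax(-1, v))
    if (length(v) < 2 || stats::sd(v) == 0) {
      return(list(class = samples$classes[j], degenerate = TRUE))
    }
    h <- bin_width(v)
    grid <- seq(min(v) - 3 * h, max(v) + 3 * h, length.out = grid_n)
    Pd <- estimate_density(v, grid, h)
    U <- -log(pmax(Pd, 1e-12))
    at <- find_attractors(Pd, grid, prominence = prominence,
                          min_rel_prominence = min_rel_prominence)
    list(class = samples$classes[j], degenerate = FALSE, n = length(v),
         h = h, grid = grid, Pd = Pd, U = U,
         attractors = at$attractors, repellors = at$repellors,
         attractor_index = at$attractor_index,
         repellor_index = at$repellor_index)
  })
  structure(list(classes = samples$classes, per_class = per_class,
                 provenance = samples$provenance, prominence = prominence),
            class = "potential_landscape")
}

#' @export
print.potential_landscape <- function(x, ...) {
  cat(sprintf("Potential landscape (%s data): %d stress class(es), prominence %.2g\n",
              x$provenance, length(x$classes), x$prominence))
  for (pc in x$per_class) {
    if (isTRUE(pc$degenerate)) {
      cat(sprintf("  class %-8g degenerate sample (skipped)\n", pc$class))
    } else {
      cat(sprintf("  class %-8g n = %-6d h = %-8.4g attractors: %s\n",
                  pc$class, pc$n, pc$h,
                  paste(signif(pc$attractors, 4), collapse = ", ")))
    }
  }
  invisible(x)
}

#' @export
plot.potential_landscape <- function(x, what = c("U", "Pd"), ...) {
  what <- match.arg(what)
  ok <- Filter(function(pc) !isTRUE(pc$degenerate), x$per_class)
  op <- graphics::par(mfrow = c(length(ok), 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  for (pc in ok) {
    graphics::plot(pc$grid, pc[[what]], type = "l",
                   xlab = "z", ylab = sprintf("%s (class %g)", what, pc$class),
                   ...)
    graphics::points(pc$attractors,
                     pc[[what]][pc$attractor_index], pch = 19)
    graphics::points(pc$repellors,
                     pc[[what]][pc$repellor_index], pch = 1)
  }
  invisible(x)
}

#' Summarise a potential landscape as a data frame
#'
#' One row per class: sample size, bandwidth, attractor count and
#' positions, repellor count.
#'
#' @param object A `potential_landscape`.
#' @param ... Unused.
#' @return A data frame.
#' @export
summary.potential_landscape <- function(object, ...) {
  do.call(rbind, lapply(object$per_class, function(pc) {
    if (isTRUE(pc$degenerate))
      return(data.frame(class = pc$class, n = NA, h = NA, n_attractors = NA,
                        attractors = NA_character_, n_repellors = NA))
    data.frame(class = pc$class, n = pc$n, h = pc$h,
               n_attractors = length(pc$attractors),
               attractors = paste(signif(pc$attractors, 6), collapse = ";"),
               n_repellors = length(pc$repellors))
  }))
}
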