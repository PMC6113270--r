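test_that("normal-reference width follows 1.06 s n^(-1/5) and scales with the data", {
  x32 <- rnorm(32)
  x32 <- (x32 - mean(x32)) / sd(x32)          # s = 1, n = 32 exactly
  expect_equal(bin_width(x32), 1.06 * 32^(-0.2))  # = 0.53
  expect_equal(bin_width(x32), 0.53, tolerance = 1e-12)
  set.seed(31)
  big <- rnorm(31250, 8000, 1200)
  expect_equal(bin_width(big), 1.06 * sd(big) * 31250^(-0.2), tolerance = 1e-12)
  expect_equal(1.06 * 1200 * 31250^(-0.2), 160.5, tolerance = 1e-3)
  x <- rnorm(100)
  expect_equal(bin_width(3.7 * x), 3.7 * bin_width(x))
  expect_error(bin_width(1), "degenerate")
  expect_error(bin_width(rep(2, 50)), "degenerate")
})

test_that("grid density equals the explicit Gaussian kernel sum", {
  set.seed(32)
  z <- c(rnorm(150, 0, 1), rnorm(50, 6, 0.5))
  g <- seq(-4, 8, length.out = 101)
  h <- bin_width(z)
  pd <- estimate_density(z, g, h)
  brute <- vapply(g, function(x) sum(dnorm((x - z) / h)) / (length(z) * h),
                  numeric(1))
  expect_equal(pd, brute, tolerance = 1e-12)
  # independent route: stats::density with the same kernel sd
  ref <- stats::density(z, bw = h, kernel = "gaussian", n = 512,
                        from = min(g), to = max(g))
  expect_equal(pd, stats::approx(ref$x, ref$y, xout = g)$y, tolerance = 5e-3)
  # normalisation over a grid spanning the sample
  wide <- seq(min(z) - 4 * h, max(z) + 4 * h, length.out = 512)
  pdw <- estimate_density(z, wide, h)
  expect_equal(sum(diff(wide) * (pdw[-1] + pdw[-512]) / 2), 1,
               tolerance = 0.01)
  expect_error(estimate_density(numeric(0), g, 1), "empty")
  expect_error(estimate_density(z, g, 0), "positive")
})

test_that("a point mass yields a symmetric single peak at the value", {
  g <- seq(-1, 3, length.out = 201)
  pd <- estimate_density(rep(1, 40), g, h = 0.25)
  expect_equal(g[which.max(pd)], 1)
  expect_equal(pd[g == 0.5], pd[g == 1.5])   # symmetry about the value
  expect_equal(pd[g == 0], pd[g == 2])
})

test_that("attractor search finds modes by prominence, repellors between them", {
  set.seed(33)
  uni <- rnorm(4000, 10, 2)
  g <- seq(0, 20, length.out = 512)
  a1 <- find_attractors(estimate_density(uni, g, bin_width(uni)), g)
  expect_length(a1$attractors, 1)
  expect_length(a1$repellors, 0)
  expect_equal(a1$attractors, 10, tolerance = 0.5)

  mix <- c(rnorm(2500, 500, 150), rnorm(2500, 7500, 800))
  h <- bin_width(mix)
  g2 <- seq(min(mix) - 3 * h, max(mix) + 3 * h, length.out = 512)
  pd <- estimate_density(mix, g2, h)
  a2 <- find_attractors(pd, g2)
  expect_length(a2$attractors, 2)
  expect_length(a2$repellors, 1)
  expect_lt(abs(a2$attractors[1] - 500), 2 * h)
  expect_lt(abs(a2$attractors[2] - 7500), 2 * h)
  expect_true(a2$repellors > a2$attractors[1] && a2$repellors < a2$attractors[2])
  # attractors are equivalently minima of the potential U = -log Pd
  U <- -log(pmax(pd, 1e-12))
  expect_equal(g2[which.max(pd)], g2[which.min(U)])
  # flat density: no peaks, empty result, no error
  flat <- find_attractors(rep(1, 100), seq_len(100))
  expect_length(flat$attractors, 0)
  expect_error(find_attractors(c(1, 2), 1:2), "at least 3")
})

test_that("attractor structure is invariant to permutation and affine rescaling", {
  set.seed(34)
  mix <- c(rnorm(1500, 0.1, 0.05), rnorm(1500, 0.6, 0.08))
  landscape_of <- function(v) {
    h <- bin_width(v)
    g <- seq(min(v) - 3 * h, max(v) + 3 * h, length.out = 512)
    find_attractors(estimate_density(v, g, h), g)
  }
  base <- landscape_of(mix)
  perm <- landscape_of(sample(mix))
  expect_equal(perm$attractors, base$attractors)
  resc <- landscape_of(1000 * mix + 50)
  expect_length(resc$attractors, length(base$attractors))
  expect_equal(resc$attractors, 1000 * base$attractors + 50, tolerance = 1e-6)
})

test_that("per-class landscapes keep ordering, flag degenerate classes, and alternate", {
  set.seed(35)
  scs <- stress_classed_samples(
    classes = c(0.0, 0.05, 0.1),
    samples = list(rnorm(3000, 7800, 900),
                   c(rnorm(1500, 100, 80), rnorm(1500, 7000, 900)),
                   rep(5, 100)),
    provenance = "model")
  pl <- potential_landscape(scs)
  expect_equal(pl$classes, c(0, 0.05, 0.1))
  expect_length(pl$per_class[[1]]$attractors, 1)
  expect_length(pl$per_class[[2]]$attractors, 2)
  expect_true(pl$per_class[[3]]$degenerate)
  for (pc in pl$per_class[1:2]) {
    expect_equal(length(pc$repellors), length(pc$attractors) - 1)
    if (length(pc$repellors)) {
      interleaved <- sort(c(pc$attractors, pc$repellors))
      expect_equal(interleaved, as.vector(rbind(pc$attractors,
                                                c(pc$repellors, NA)))[
                                                  seq_along(interleaved)])
    }
    expect_true(all(is.finite(pc$U[pc$Pd > 0])))
    # argmax Pd = argmin U on the class grid
    expect_equal(pc$grid[which.max(pc$Pd)], pc$grid[which.min(pc$U)])
  }
  # NDVI clamping
  pl2 <- potential_landscape(c(rnorm(500, 0.9, 0.2), 1.5, -1.5), ndvi = TRUE)
  expect_lte(max(pl2$per_class[[1]]$attractors), 1 + 3 * pl2$per_class[[1]]$h)
})
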