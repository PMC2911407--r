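# Structural observables: pair distances, p(r), r_Delta statistics, g(r),
# S(q), projections and peak allocation.

test_that("pair distance streaming matches the brute-force oracle exactly", {
  # trivial two-nucleosome case
  fx <- fixture_fiber("rod", n = 2, spacing_nm = 20)
  pd <- pair_distances(fx)
  expect_equal(pd, data.frame(delta = 1L, r = 20))

  # grown fiber <= 50 nucleosomes: identical multiset to O(N^2) distances
  set.seed(8)
  f <- grow_fiber(sim_config(regular_params(), fiber_length_bp = 196 * 50,
                             seed = 8))
  pd <- pair_distances(f, cutoff_nm = Inf, delta_max = Inf)
  expect_equal(sort(pd$r), brute_force_pairs(f$centers), tolerance = 1e-12)

  # histogram counts equal brute-force binning, bin by bin
  for (cut in c(40, 100)) {
    h <- conditional_probability(f, bin_width_nm = 0.2, cutoff_nm = cut)
    bf <- brute_force_pairs(f$centers, cutoff_nm = cut)
    expect_equal(h$counts,
                 as.numeric(table(cut(bf, h$breaks, right = FALSE))),
                 label = sprintf("cutoff %g", cut))
    expect_equal(h$n_pairs_within, length(bf))
  }
})

test_that("regular ensembles attain their minimum mean distance at two repeats", {
  ens <- small_ensemble(n_fibers = 8, n_rep = 150, seed = 41)
  rd <- r_delta_stats(ens, delta_max = 10)
  expect_identical(which.min(rd$mean), 2L)
  # spatial spread broadens with genomic separation (trend; the zigzag
  # parity makes sigma oscillate around the trend)
  expect_gt(rd$sd[10], rd$sd[2])
  expect_gt(coef(lm(sd ~ delta, rd[2:10, ]))[["delta"]], 0)
})

test_that("p(r) normalizations satisfy their stated identities", {
  set.seed(20)
  f <- grow_fiber(sim_config(regular_params(), fiber_length_bp = 196 * 60,
                             seed = 20))
  h <- conditional_probability(f, bin_width_nm = 0.2, cutoff_nm = 40)
  pu <- as_probability(h, "unit_mass")
  expect_equal(sum(pu$p) * h$bin_width_nm, 1, tolerance = 1e-12)
  pa <- as_probability(h, "all_pairs")
  expect_equal(sum(pa$p) * h$bin_width_nm,
               h$n_pairs_within / h$n_pairs_total, tolerance = 1e-12)
})

test_that("p(r) is the exact per-bin superposition of its r_Delta components", {
  set.seed(9)
  f <- grow_fiber(sim_config(e2a_params(), fiber_length_bp = 196 * 60,
                             seed = 9))
  h <- conditional_probability(f, bin_width_nm = 0.2, cutoff_nm = 60)
  pd <- pair_distances(f, cutoff_nm = 60, delta_max = Inf)
  comp <- matrix(0, length(h$counts), length(unique(pd$delta)))
  for (j in seq_along(unique(pd$delta))) {
    d <- unique(pd$delta)[j]
    comp[, j] <- as.numeric(table(cut(pd$r[pd$delta == d], h$breaks,
                                      right = FALSE)))
  }
  expect_equal(rowSums(comp), h$counts)
})

test_that("uniform points on a ring reproduce the analytic chord-length law", {
  set.seed(77)
  a <- 25
  th <- runif(4000, 0, 2 * pi)
  pts <- cbind(a * cos(th), a * sin(th), 0)
  r <- brute_force_pairs(pts)
  # analytic CDF of the chord length: F(r) = (2/pi) asin(r / (2a))
  F <- function(r) 2 / pi * asin(pmin(1, r / (2 * a)))
  ec <- ecdf(r)
  grid <- seq(1, 2 * a - 1, length.out = 200)
  expect_lt(max(abs(ec(grid) - F(grid))), 0.02)
})

test_that("g(r) is calibrated to the mean density of the bounded system", {
  # ideal gas: Poisson points on scales far above the cutoff give g ~ 1
  # inside the analysis sphere
  gas <- fixture_fiber("random_gas", n = 8000, seed = 5, radius_nm = 400)
  h <- conditional_probability(gas$centers, bin_width_nm = 4, cutoff_nm = 40)
  g <- pair_distribution_3d(h)
  mid <- g$r > 8 & g$r < 40
  expect_lt(mean(abs(g$g[mid] - 1)), 0.1)

  # a single fixed pair against the analytic shell value
  r0 <- 17.3
  pts <- rbind(c(0, 0, 0), c(r0, 0, 0))
  h1 <- conditional_probability(pts, bin_width_nm = 0.2, cutoff_nm = 40)
  g1 <- pair_distribution_3d(h1)
  rho <- 1 / (4 / 3 * pi * 40^3)  # one neighbour per reference sphere
  bin_r <- g1$r[which(g1$g > 0)]
  expect_equal(bin_r, floor(r0 / 0.2) * 0.2 + 0.1)
  expect_equal(max(g1$g), 1 / (4 * pi * bin_r^2 * 0.2 * rho),
               tolerance = 1e-9)

  # chromatin: away from the zigzag shells, most of the 40 nm sphere is
  # empty, so g sits below the mean-density level there
  ens <- small_ensemble(n_fibers = 6, n_rep = 200, seed = 6)
  ge <- pair_distribution_3d(conditional_probability(ens, 0.5, 40))
  expect_lt(stats::median(ge$g[ge$r > 14 & ge$r < 28]), 1)
})

test_that("the scattering transform matches its closed forms and the Debye sum", {
  # g identically 1 has no correlation part
  gser <- data.frame(r = seq(0.1, 39.9, 0.2), g = 1)
  attr(gser, "rho") <- 1e-3
  s <- scattering_function(gser, q = c(0.1, 0.5, 1))
  expect_equal(s$S, rep(1, 3), tolerance = 1e-12)

  # Gaussian pair correlation: S(q) = 1 + rho A (2 pi)^(3/2) s^3 e^(-q^2 s^2/2)
  sg <- 3; A <- 0.4; rho <- 2e-3
  r <- seq(0.005, 60, 0.01)
  gser <- data.frame(r = r, g = 1 + A * exp(-r^2 / (2 * sg^2)))
  attr(gser, "rho") <- rho
  q <- seq(0.2, 2, 0.3)
  s <- scattering_function(gser, q)
  expect_equal(s$S, 1 + rho * A * (2 * pi)^1.5 * sg^3 * exp(-q^2 * sg^2 / 2),
               tolerance = 1e-4)

  # small point set: pipeline S(q) equals the direct Debye sum up to the
  # analytic uniform-background term of the bounded system
  set.seed(12)
  pts <- matrix(rnorm(3 * 40, sd = 8), ncol = 3)
  R <- 40
  h <- conditional_probability(pts, bin_width_nm = 0.05, cutoff_nm = R)
  g <- pair_distribution_3d(h)
  rho <- attr(g, "rho")
  q <- seq(0.1, 1.5, 0.2)
  s <- scattering_function(g, q)
  rij <- brute_force_pairs(pts, cutoff_nm = R)
  debye <- vapply(q, function(qq)
    1 + 2 / nrow(pts) * sum(sin(qq * rij) / (qq * rij)), numeric(1))
  backg <- vapply(q, function(qq)
    rho * 4 * pi * (sin(qq * R) - qq * R * cos(qq * R)) / qq^3, numeric(1))
  expect_equal(s$S, debye - backg, tolerance = 2e-2)
})

test_that("projection preserves in-plane distances and can only shorten pairs", {
  fx <- fixture_fiber("random_gas", n = 200, seed = 3)
  flat <- fx
  flat$centers[, 3] <- 0
  pr <- project_fiber(flat, axis = c(0, 0, 1))
  expect_equal(brute_force_pairs(pr$points), brute_force_pairs(flat$centers),
               tolerance = 1e-12)

  set.seed(90)
  pr2 <- project_fiber(fx, axis = "random")
  d3 <- as.numeric(dist(fx$centers))
  d2 <- as.numeric(dist(pr2$points))
  expect_true(all(d2 <= d3 + 1e-9))
})

test_that("random-axis projection of a fixed pair follows the analytic density", {
  # distance r' of a projected pair: density r'/(r sqrt(r^2 - r'^2)),
  # CDF 1 - sqrt(1 - (r'/r)^2)
  set.seed(14)
  r0 <- 30
  n <- 1e5
  z <- runif(n, -1, 1); ph <- runif(n, 0, 2 * pi)
  axes <- cbind(sqrt(1 - z^2) * cos(ph), sqrt(1 - z^2) * sin(ph), z)
  v <- c(r0, 0, 0)
  proj <- sqrt(r0^2 - (axes %*% v)^2)
  ks <- suppressWarnings(
    ks.test(proj, function(x) 1 - sqrt(pmax(0, 1 - (x / r0)^2))))
  expect_gt(ks$p.value, 0.01)

  # the same law drives project_fiber on a two-point fiber
  fx <- fixture_fiber("rod", n = 2, spacing_nm = r0)
  d <- replicate(2000, dist(project_fiber(fx, axis = "random")$points)[1])
  ks2 <- suppressWarnings(
    ks.test(d, function(x) 1 - sqrt(pmax(0, 1 - (x / r0)^2))))
  expect_gt(ks2$p.value, 0.01)
})

test_that("g2D of uniform points in a plane is flat at one", {
  set.seed(33)
  n <- 6000
  rr <- 150 * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  pts <- cbind(rr * cos(th), rr * sin(th))
  h <- conditional_probability(pts, bin_width_nm = 2, cutoff_nm = 40)
  expect_identical(h$dimension, 2L)
  g <- pair_distribution_2d(h)
  mid <- g$r > 4 & g$r < 40
  expect_lt(mean(abs(g$g[mid] - 1)), 0.1)
})

test_that("projected fibers gain mass below 10 nm that 3D ensembles forbid", {
  ens <- small_ensemble(n_fibers = 6, n_rep = 200, seed = 52,
                        params = e2a_params())
  p3 <- as_probability(conditional_probability(ens, 0.2, 40))
  expect_identical(sum(p3$p[p3$r < ens$config$params$nucleosome_height_nm]),
                   0)
  set.seed(52)
  pr <- project_fiber(ens, axis = "random")
  p2 <- as_probability(conditional_probability(pr, 0.2, 40))
  expect_gt(sum(p2$p[p2$r < 10]), 0)
})

test_that("r_Delta statistics: rigid helix has zero spread; conventions differ on skips", {
  fib <- constant_angle_fiber(20)
  rd <- r_delta_stats(fib, delta_max = 6)
  expect_true(all(rd$sd < 1e-9))
  expect_true(all(rd$mode >= 0 & rd$mode <= max(pair_distances(fib)$r)))

  # a nucleosome skip removes Delta = 1 pairs in genomic units but not in
  # ordinal units
  p <- e2a_params()
  mask <- defect_mask(c(rep("regular", 10), "nuc_skip",
                        rep("regular", 10)), p)
  set.seed(2)
  f <- grow_fiber(sim_config(p, fiber_length_bp = 21 * p$nrl_bp, seed = 2),
                  mask = mask)
  gen <- pair_distances(f, delta_max = 1, delta_units = "genomic")
  ord <- pair_distances(f, delta_max = 1, delta_units = "ordinal")
  expect_identical(nrow(gen), 18L)  # 20 present nucleosomes, one index gap
  expect_identical(nrow(ord), n_nucleosomes(f) - 1L)
  expect_identical(nrow(ord), nrow(gen) + 1L)  # the skip-straddling pair
})

test_that("peak detection finds and allocates constructed mixtures", {
  # two clean Gaussians
  r <- seq(0.5, 120, 0.5)
  p <- dnorm(r, 40, 3) + 0.6 * dnorm(r, 80, 4)
  pk <- detect_peaks(data.frame(r = r, p = p), smooth_bins = 1)
  expect_identical(nrow(pk), 2L)
  expect_equal(pk$position_nm, c(40, 80), tolerance = 0.02)

  # flat input: no peaks, no error
  expect_identical(nrow(detect_peaks(data.frame(r = r, p = rep(1, length(r))))),
                   0L)

  # mixture of the regular-fiber r_Delta components: the first two peaks
  # collect Delta = 2 and Delta = {1, 3}
  comp <- data.frame(
    delta = 1:10,
    mean = c(51.00, 37.55, 51.33, 68.14, 64.27, 90.04, 90.17, 106.81,
             118.87, 125.06),
    sd = c(0.63, 7.16, 4.00, 7.17, 8.27, 6.08, 11.13, 7.94, 10.88, 11.55))
  comp$mode <- comp$mean
  comp$n <- 1000L
  class(comp) <- c("rdelta_stats", "data.frame")
  r <- seq(0.1, 160, 0.2)
  pr <- rowSums(vapply(1:10, function(d)
    dnorm(r, comp$mean[d], comp$sd[d]), numeric(length(r))))
  pk <- detect_peaks(data.frame(r = r, p = pr), components = comp,
                     smooth_bins = 1, min_prominence_frac = 0.002)
  expect_gte(nrow(pk), 3L)
  expect_identical(pk$delta[[1]], 2L)
  expect_identical(pk$delta[[2]], c(1L, 3L))
})
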