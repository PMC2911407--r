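# Contact (loop) detection, interaction maps, center cuts, gap widths and
# loop-size distributions.

test_that("contact detection matches brute force and constructed fixtures", {
  # a straight rod folds no loops beyond its bonded neighbourhood
  rod <- fixture_fiber("rod", n = 30, spacing_nm = 20)
  expect_identical(nrow(detect_contacts(rod, min_separation_bp = 2 * 196)),
                   0L)

  # hairpin with a 30 nm tip closure: with the genomic exclusion set between
  # the 3rd and the outermost cross-arm pair, exactly the outermost pair
  # remains (construction: arms 20 nm apart in z, 30 nm apart in x)
  hp <- fixture_fiber("hairpin", n = 10, spacing_nm = 20, tip_gap_nm = 30)
  cts <- detect_contacts(hp, contact_radius_nm = 35,
                         min_separation_bp = 1500)
  expect_identical(nrow(cts), 1L)
  expect_equal(cts$loop_bp, diff(hp$nucleosome_bp[c(1, 10)]))

  # grid-accelerated detection is exactly brute force (<= 100 sites)
  gas <- fixture_fiber("random_gas", n = 100, seed = 21, radius_nm = 60)
  for (min_sep in c(0, 196, 1000)) {
    cts <- detect_contacts(gas, contact_radius_nm = 35,
                           min_separation_bp = min_sep)
    d <- as.matrix(dist(gas$centers))
    bpd <- abs(outer(gas$nucleosome_bp, gas$nucleosome_bp, "-"))
    brute <- which(d <= 35 & bpd >= min_sep & upper.tri(d), arr.ind = TRUE)
    expect_identical(nrow(cts), nrow(brute))
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    expect_setequal(key(cts$i_bp, cts$j_bp),
                    key(gas$nucleosome_bp[brute[, 1]],
                        gas$nucleosome_bp[brute[, 2]]))
  }
})

test_that("interaction maps are symmetric, normalized and translation-consistent", {
  empty <- structure(
    data.frame(i_bp = numeric(), j_bp = numeric(), loop_bp = numeric(),
               fiber = integer()),
    class = c("loop_records", "data.frame"))
  m0 <- interaction_map(empty, bin_bp = 1000, genomic_length_bp = 10000)
  expect_true(all(m0$matrix == 0))
  expect_identical(dim(m0$matrix), c(10L, 10L))

  one <- empty
  one[1, ] <- list(2100, 7300, 5200, 1L)
  m1 <- interaction_map(one, bin_bp = 1000, genomic_length_bp = 10000)
  expect_identical(sum(m1$matrix != 0), 2L)
  expect_equal(m1$matrix[3, 8], 1)
  expect_equal(m1$matrix, t(m1$matrix))

  # shifting the genomic origin by whole bins shifts the map identically
  shifted <- one
  shifted$i_bp <- shifted$i_bp + 2000
  shifted$j_bp <- shifted$j_bp + 2000
  m2 <- interaction_map(shifted, bin_bp = 1000, genomic_length_bp = 12000)
  expect_equal(m2$matrix[5, 10], m1$matrix[3, 8])

  # per-pair normalization sums to one over the upper triangle
  two <- rbind(one, data.frame(i_bp = 500, j_bp = 9800, loop_bp = 9300,
                               fiber = 2L))
  class(two) <- class(one)
  mp <- interaction_map(two, bin_bp = 1000, genomic_length_bp = 10000,
                        normalization = "per_pair")
  expect_equal(sum(mp$matrix) / 2, 1)
})

test_that("center cuts are even for symmetric maps and localize delta contacts", {
  nb <- 21L
  m <- matrix(0, nb, nb)
  ctr <- 11
  for (k in c(3, 6)) {
    m[ctr, ctr + k] <- m[ctr + k, ctr] <- 2
    m[ctr, ctr - k] <- m[ctr - k, ctr] <- 2
  }
  map <- structure(list(matrix = m, bin_bp = 1000,
                        positions_bp = (seq_len(nb) - 1) * 1000,
                        n_fibers = 1L, normalization = "per_fiber"),
                   class = "contact_map")
  cc <- center_cut(map)
  expect_identical(nrow(cc), nb)
  expect_equal(cc$frequency[cc$distance_bp > 0],
               rev(cc$frequency[cc$distance_bp < 0]))
  expect_setequal(cc$distance_bp[cc$frequency > 0],
                  c(-6000, -3000, 3000, 6000))
})

test_that("gap widths cover the boxcar, all-zero and threshold cases", {
  d <- seq(-10000, 10000, 1000)
  prof <- function(f) structure(data.frame(distance_bp = d, frequency = f),
                                bin_bp = 1000,
                                class = c("center_cut", "data.frame"))
  # all-zero profile: the full width
  expect_equal(as.numeric(gap_width(prof(rep(0, 21)))), 21000)
  # boxcar with a 5-bin central notch
  f <- rep(10, 21); f[9:13] <- 0
  expect_equal(as.numeric(gap_width(prof(f))), 5000)
  expect_equal(attr(gap_width(prof(f)), "kbp"), 5)
  # no gap when the center is above threshold
  f2 <- rep(10, 21)
  expect_equal(as.numeric(gap_width(prof(f2))), 0)
  # threshold fraction moves the boundary
  f3 <- rep(10, 21); f3[10:12] <- 0.5
  expect_equal(as.numeric(gap_width(prof(f3), threshold_fraction = 0.1)),
               3000)
  expect_equal(as.numeric(gap_width(prof(f3), threshold_fraction = 0.01)),
               0)
})

test_that("loop-size distributions bin constructed loops exactly", {
  expect_identical(nrow(loop_size_distribution(
    structure(data.frame(i_bp = numeric(), j_bp = numeric(),
                         loop_bp = numeric(), fiber = integer()),
              class = c("loop_records", "data.frame")))), 0L)

  recs <- structure(
    data.frame(i_bp = c(0, 0), j_bp = c(5000, 20000),
               loop_bp = c(5000, 20000), fiber = c(1L, 1L)),
    class = c("loop_records", "data.frame"))
  h <- loop_size_distribution(recs, bin_kbp = 1)
  expect_identical(sum(h$count > 0), 2L)
  expect_equal(h$count[h$loop_kbp == 5.5], 1)  # 5 kbp opens bin [5, 6)
  expect_equal(attr(h, "min_loop_kbp"), 5)
  expect_equal(sum(h$density) * 1, 1)
})

test_that("interaction tables round-trip and reject malformed input", {
  m <- matrix(c(1, 0.5, 0, 0.5, 2, 0.25, 0, 0.25, 3), 3, 3)
  map <- structure(list(matrix = m, bin_bp = 2000,
                        positions_bp = c(0, 2000, 4000), n_fibers = 4L,
                        normalization = "per_fiber"),
                   class = "contact_map")
  path <- tempfile(fileext = ".tsv")
  write_interaction_table(map, path)
  back <- read_interaction_table(path)
  expect_equal(back$matrix, m)
  expect_equal(back$positions_bp, c(0, 2000, 4000))
  # writing the re-read map reproduces the file byte for byte
  path2 <- tempfile(fileext = ".tsv")
  back$n_fibers <- map$n_fibers; back$normalization <- map$normalization
  write_interaction_table(back, path2)
  expect_identical(readLines(path2), readLines(path))

  # asymmetric input is symmetrized with a warning
  asym <- m; asym[1, 2] <- 0.9
  lines <- readLines(path)
  rows <- strsplit(lines[3:5], "\t")
  rows[[1]][3] <- "0.9"
  lines[3:5] <- vapply(rows, paste, character(1), collapse = "\t")
  writeLines(lines, path)
  expect_warning(sym <- read_interaction_table(path), "symmetrized")
  expect_equal(sym$matrix[1, 2], (0.9 + 0.5) / 2)

  # missing header and non-numeric entries carry line information
  writeLines(c("1\t2", "3\t4"), path)
  expect_error(read_interaction_table(path), "header")
  writeLines(c("\t0\t2000", "0\t1\tx", "2000\t1\t2"), path)
  expect_error(read_interaction_table(path), "line 2")
})

test_that("depleted fibers loop on the kbp scale that regular fibers exclude", {
  # matched seeds, 160 kbp fibers
  n <- 14
  reg <- simulate_ensemble(sim_config(regular_params(),
                                      fiber_length_bp = 160000,
                                      n_fibers = n, seed = 19))
  dep <- simulate_ensemble(sim_config(e2a_params(),
                                      fiber_length_bp = 160000,
                                      n_fibers = n, seed = 19))
  c_reg <- ensemble_contacts(reg)
  c_dep <- ensemble_contacts(dep)
  # depleted fibers loop abundantly at or below 10 kbp; regular fibers do
  # not reach that scale
  expect_gt(sum(c_dep$loop_bp <= 10000), 10 * sum(c_reg$loop_bp <= 10000))
  if (nrow(c_reg) > 0)
    expect_gt(min(c_reg$loop_bp), min(c_dep$loop_bp))
})
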