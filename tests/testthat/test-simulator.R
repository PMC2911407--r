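# Chain growth, defect sampling, Monte Carlo equilibration and ensemble
# reproducibility.

test_that("defect sampling matches the binomial rates and is mutually exclusive", {
  p <- e2a_params()
  set.seed(101)
  n <- 200000L
  m <- draw_defects(p, n)
  expect_true(all(m %in% c("regular", "lh_skip", "nuc_skip")))

  k_nuc <- sum(m == "nuc_skip")
  se_nuc <- sqrt(n * p$p_nuc_skip * (1 - p$p_nuc_skip))
  expect_lt(abs(k_nuc - n * p$p_nuc_skip), 3 * se_nuc)

  # linker-histone skips are drawn conditionally on no nucleosome skip
  n_eligible <- n - k_nuc
  k_lh <- sum(m == "lh_skip")
  se_lh <- sqrt(n_eligible * p$p_lh_skip * (1 - p$p_lh_skip))
  expect_lt(abs(k_lh - n_eligible * p$p_lh_skip), 3 * se_lh)

  expect_identical(draw_defects(regular_params(), 500),
                   defect_mask(rep("regular", 500), regular_params()))
})

test_that("growth honours the defect mask: lengths, index gaps, naked runs", {
  p <- e2a_params()
  cfg <- sim_config(p, fiber_length_bp = 20 * p$nrl_bp, seed = 3)
  mask <- defect_mask(c(rep("regular", 6), "nuc_skip", "nuc_skip",
                        rep("regular", 5), "lh_skip", rep("regular", 6)), p)
  set.seed(3)
  f <- grow_fiber(cfg, mask = mask)
  expect_s3_class(f, "fiber_conformation")
  expect_identical(n_nucleosomes(f), 18L)
  expect_identical(f$genomic_index, c(0:5, 8:19))
  expect_true(any(f$lh_skip))
  expect_gt(nrow(f$dna_path), 0)
  # naked stretch contour equals (2 * NRL + linker) bp at the B-DNA rise
  run_bp <- 2 * p$nrl_bp + p$linker_bp
  seg_len <- sqrt(rowSums(diff(rbind(f$exit[6, ], f$dna_path))^2))
  expect_equal(sum(seg_len), run_bp * p$rise_nm_per_bp, tolerance = 1e-9)
  validate_fiber(f)

  # one repeat -> single nucleosome at the origin
  cfg1 <- sim_config(p, fiber_length_bp = p$nrl_bp, seed = 5)
  set.seed(5)
  f1 <- grow_fiber(cfg1, mask = defect_mask("regular", p))
  expect_identical(n_nucleosomes(f1), 1L)
  expect_equal(as.numeric(f1$centers), c(0, 0, 0))
})

test_that("ensembles are reproducible from the seed, fiber by fiber", {
  cfg <- sim_config(regular_params(), fiber_length_bp = 196 * 40,
                    n_fibers = 3, seed = 11)
  e1 <- simulate_ensemble(cfg)
  e2 <- simulate_ensemble(cfg)
  for (i in 1:3)
    expect_identical(e1$fibers[[i]]$centers, e2$fibers[[i]]$centers)
  e3 <- simulate_ensemble(sim_config(regular_params(),
                                     fiber_length_bp = 196 * 40,
                                     n_fibers = 3, seed = 12))
  expect_false(identical(e1$fibers[[1]]$centers, e3$fibers[[1]]$centers))

  # zero-variance distributions make the fiber deterministic across seeds
  p0 <- regular_params(alpha_sd = 0, beta_sd = 0, linker_length_sd_nm = 0)
  fa <- simulate_ensemble(sim_config(p0, fiber_length_bp = 196 * 15,
                                     seed = 1))$fibers[[1]]
  fb <- simulate_ensemble(sim_config(p0, fiber_length_bp = 196 * 15,
                                     seed = 99))$fibers[[1]]
  expect_equal(fa$centers, fb$centers, tolerance = 1e-12)
})

test_that("a 160 kbp fiber carries ~816 nucleosomes minus the skips", {
  p <- e2a_params()
  cfg <- sim_config(regular_params(), fiber_length_bp = 160000, seed = 2)
  set.seed(2)
  f <- grow_fiber(cfg)
  expect_identical(n_nucleosomes(f), 816L)  # floor(160000 / 196)

  set.seed(2)
  cfgd <- sim_config(p, fiber_length_bp = 160000, seed = 2)
  fd <- grow_fiber(cfgd)
  expect_identical(n_nucleosomes(fd),
                   sum(unclass(fd$defect_mask) != "nuc_skip"))
  expect_lt(n_nucleosomes(fd), 816L)
})

test_that("grown ensembles respect the excluded volume", {
  ens <- small_ensemble(n_fibers = 4, n_rep = 100, seed = 23)
  p <- ens$config$params
  for (f in ens$fibers) {
    expect_gte(min(dist(f$centers)), p$nucleosome_height_nm)
    aud <- audit_excluded_volume(f)
    expect_false(aud$overlap)
  }
  # consequently the 3D pair histogram is empty below the contact distance
  h <- conditional_probability(ens, bin_width_nm = 0.2, cutoff_nm = 40)
  below <- h$mids < p$nucleosome_height_nm
  expect_identical(sum(h$counts[below]), 0)
})

test_that("depletion shrinks the fiber: end-to-end and stiffness decrease", {
  n_rep <- 300
  reg <- small_ensemble(n_fibers = 12, n_rep = n_rep, seed = 7,
                        params = regular_params())
  dep <- small_ensemble(n_fibers = 12, n_rep = n_rep, seed = 7,
                        params = e2a_params())
  expect_lt(end_to_end(dep)$mean_r2, end_to_end(reg)$mean_r2)
  lp_reg <- persistence_length(reg, n_boot = 0)$lp_nm
  lp_dep <- persistence_length(dep, n_boot = 0)$lp_nm
  expect_lt(lp_dep, lp_reg)

  # each defect type alone also softens the fiber (monotone response)
  nuc_only <- small_ensemble(n_fibers = 12, n_rep = n_rep, seed = 7,
                             params = e2a_params(p_lh_skip = 0))
  lh_only <- small_ensemble(n_fibers = 12, n_rep = n_rep, seed = 7,
                            params = e2a_params(p_nuc_skip = 0))
  expect_lt(persistence_length(nuc_only, n_boot = 0)$lp_nm, lp_reg)
  expect_lt(persistence_length(lh_only, n_boot = 0)$lp_nm, lp_reg)
})

test_that("naked DNA reproduces worm-like-chain statistics", {
  # a fiber of nucleosome skips only is a pure WLC path at the B-DNA rise
  p <- e2a_params()
  cfg <- sim_config(p, fiber_length_bp = 300 * p$nrl_bp, seed = 13)
  set.seed(13)
  mask <- defect_mask(rep("nuc_skip", 300), p)
  paths <- lapply(1:12, function(i) grow_fiber(cfg, mask = mask)$dna_path)
  sr <- persistence_length(paths, window = 1, n_boot = 0,
                           genomic_length_bp = NA)
  expect_equal(sr$lp_nm, p$naked_dna_lp_nm, tolerance = 0.10)
})

test_that("pivot Monte Carlo preserves the growth ensemble", {
  p <- regular_params()
  cfg0 <- sim_config(p, fiber_length_bp = 196 * 40, n_fibers = 24, seed = 31,
                     mc_moves_per_site = 0)
  cfg1 <- sim_config(p, fiber_length_bp = 196 * 40, n_fibers = 24, seed = 31,
                     mc_moves_per_site = 8)
  set.seed(1); grow <- end_to_end(simulate_ensemble(cfg0))
  set.seed(2); mc <- end_to_end(simulate_ensemble(cfg1))
  z <- abs(grow$mean_r2 - mc$mean_r2) / sqrt(grow$se^2 + mc$se^2)
  expect_lt(z, 3)

  # zero sweeps is the identity
  set.seed(4)
  f <- grow_fiber(sim_config(p, fiber_length_bp = 196 * 20, seed = 4))
  expect_identical(mc_equilibrate(f, cfg0, sweeps = 0), f)

  # MC on a fiber keeps every structural invariant
  set.seed(5)
  fd <- grow_fiber(sim_config(e2a_params(), fiber_length_bp = 196 * 30,
                              seed = 5))
  fm <- mc_equilibrate(fd, cfg0, sweeps = 5)
  validate_fiber(fm)
  expect_false(audit_excluded_volume(fm)$overlap)
  expect_identical(fm$genomic_index, fd$genomic_index)
})

test_that("unsatisfiable excluded volume raises a growth failure with partial length", {
  # a nucleosome too fat to fit next to its neighbours cannot grow
  p <- regular_params(nucleosome_radius_nm = 40, nucleosome_height_nm = 40)
  cfg <- sim_config(p, fiber_length_bp = 196 * 10, seed = 1,
                    growth_max_retries = 5, growth_restarts = 1)
  set.seed(1)
  err <- tryCatch(grow_fiber(cfg), e2a_growth_failure = function(e) e)
  expect_s3_class(err, "e2a_growth_failure")
  expect_lt(err$partial_length_bp, 196 * 10)
})
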