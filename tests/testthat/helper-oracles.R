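# Independent oracles and small generators shared across the test files.

# worm-like chain sampler, independent of the package's growth engine
wlc_chain <- function(n_seg, seg_len, lp) {
  t <- c(0, 0, 1); n <- c(1, 0, 0)
  pts <- matrix(0, n_seg + 1, 3)
  for (i in seq_len(n_seg)) {
    b <- c(t[2] * n[3] - t[3] * n[2], t[3] * n[1] - t[1] * n[3],
           t[1] * n[2] - t[2] * n[1])
    gx <- stats::rnorm(1, 0, sqrt(seg_len / lp))
    gy <- stats::rnorm(1, 0, sqrt(seg_len / lp))
    g <- sqrt(gx^2 + gy^2); ps <- atan2(gy, gx)
    t_new <- cos(g) * t + sin(g) * (cos(ps) * n + sin(ps) * b)
    t_new <- t_new / sqrt(sum(t_new^2))
    n <- t - sum(t * t_new) * t_new
    if (sqrt(sum(n^2)) < 1e-8) n <- c(1, 0, 0) - t_new[1] * t_new
    n <- n / sqrt(sum(n^2))
    t <- t_new
    pts[i + 1, ] <- pts[i, ] + seg_len * t
  }
  pts
}

# freely jointed chain of unit-variance random bonds
fjc_chain <- function(n_bonds, b) {
  steps <- matrix(stats::rnorm(3 * n_bonds), ncol = 3)
  steps <- steps / sqrt(rowSums(steps^2)) * b
  rbind(0, apply(steps, 2, cumsum))
}

random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    if (sum(q^2) > 1e-12) break
  }
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# deterministic chain with constant angles (no noise, no excluded volume)
constant_angle_fiber <- function(n_rep = 30, alpha = NULL, beta = NULL,
                                 params = regular_params()) {
  p <- params
  p$alpha_sd <- 0; p$beta_sd <- 0; p$linker_length_sd_nm <- 0
  if (!is.null(alpha)) p$alpha_mean <- alpha
  if (!is.null(beta)) p$beta_mean <- beta
  cfg <- sim_config(p, fiber_length_bp = n_rep * p$nrl_bp, seed = 1)
  grow_fiber(cfg, mask = defect_mask(rep("regular", n_rep), p))
}

small_ensemble <- function(n_fibers = 6, n_rep = 120, seed = 17,
                           params = regular_params(), ...) {
  cfg <- sim_config(params, fiber_length_bp = n_rep * params$nrl_bp,
                    n_fibers = n_fibers, seed = seed, ...)
  simulate_ensemble(cfg)
}
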