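# Ensemble generation: defect sampling, chain growth with excluded-volume
# rejection, pivot Monte Carlo, reproducible ensembles.

#' Simulation configuration
#'
#' @param params An `"e2a_params"` object.
#' @param fiber_length_bp Genomic length of each fiber (bp); at least one
#'   nucleosome repeat.
#' @param n_fibers Number of independent fibers in the ensemble.
#' @param seed Integer RNG seed; fixes the full ensemble bit-for-bit.
#' @param growth_max_retries Maximum resampling attempts per growth step
#'   before the attempt is abandoned.
#' @param growth_restarts Whole-fiber restarts after an abandoned growth
#'   attempt (dead ends occur when a dense prefix traps the chain end);
#'   exceeding this raises a growth-failure error carrying the partial
#'   length.
#' @param mc_moves_per_site Pivot-move sweeps applied after growth (moves per
#'   chain site). The default of 0 relies on unbiased chain growth, which at
#'   the model's low clash rates already samples the athermal ensemble; see
#'   the vignette and [mc_equilibrate()].
#' @param move_set Character vector of enabled Monte Carlo moves; currently
#'   `"pivot"` (site-angle resampling with rigid downstream rotation).
#' @param defect_sampler Function `(params, n_positions)` returning a defect
#'   mask; defaults to [draw_defects()]. Pluggable so that non-i.i.d. defect
#'   models can be studied.
#' @return A `"e2a_sim_config"` object.
#' @export
sim_config <- function(params = e2a_params(), fiber_length_bp = 160000,
                       n_fibers = 1L, seed = 1L, growth_max_retries = 200L,
                       growth_restarts = 50L, mc_moves_per_site = 0L,
                       move_set = "pivot", defect_sampler = draw_defects) {
  stopifnot(inherits(params, "e2a_params"))
  if (fiber_length_bp < params$nrl_bp)
    stop("fiber_length_bp must cover at least one nucleosome repeat")
  if (n_fibers < 1) stop("n_fibers must be >= 1")
  cfg <- list(params = params, fiber_length_bp = fiber_length_bp,
              n_fibers = as.integer(n_fibers), seed = as.integer(seed),
              growth_max_retries = as.integer(growth_max_retries),
              growth_restarts = as.integer(growth_restarts),
              mc_moves_per_site = as.integer(mc_moves_per_site),
              move_set = move_set, defect_sampler = defect_sampler)
  class(cfg) <- "e2a_sim_config"
  cfg
}

#' @export
print.e2a_sim_config <- function(x, ...) {
  cat(sprintf("Simulation config: %d fiber(s) x %.1f kbp, seed %d, %d MC sweep(s)\n",
              x$n_fibers, x$fiber_length_bp / 1000, x$seed,
              x$mc_moves_per_site))
  invisible(x)
}

#' Draw histone-depletion defects
#'
#' Assigns each nucleosome repeat independently to one of three states:
#' regular, linker-histone skip, or nucleosome skip. The two depletion
#' effects are mutually exclusive at a position (a missing octamer implies
#' no histone at all), so a position is first tested for a nucleosome skip
#' and only otherwise for a linker-histone skip; marginal rates converge to
#' `p_nuc_skip` and `(1 - p_nuc_skip) * p_lh_skip` respectively, and runs of
#' consecutive nucleosome skips arise by chance.
#'
#' @param params An `"e2a_params"` object (uses `p_nuc_skip`, `p_lh_skip`).
#' @param n_positions Number of nucleosome repeats.
#' @return A `"defect_mask"`: character vector with levels `"regular"`,
#'   `"lh_skip"`, `"nuc_skip"` and attribute `runs` (data frame of
#'   consecutive nucleosome-skip runs with `start`, `length`,
#'   `naked_bp = length * nrl_bp + linker_bp`).
#' @export
draw_defects <- function(params, n_positions) {
  stopifnot(n_positions >= 1)
  u <- stats::runif(n_positions)
  mask <- rep("regular", n_positions)
  mask[u < params$p_nuc_skip] <- "nuc_skip"
  lh <- stats::runif(n_positions) < params$p_lh_skip
  mask[mask != "nuc_skip" & lh] <- "lh_skip"
  defect_mask(mask, params)
}

#' Build a defect mask from explicit states
#'
#' @param states Character vector of `"regular"`, `"lh_skip"`, `"nuc_skip"`.
#' @param params Model parameters (for the naked-DNA run lengths).
#' @return A `"defect_mask"` object.
#' @export
defect_mask <- function(states, params = e2a_params()) {
  if (!all(states %in% c("regular", "lh_skip", "nuc_skip")))
    stop("unknown defect state")
  r <- rle(states == "nuc_skip")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], length = r$lengths[r$values])
  runs$naked_bp <- runs$length * params$nrl_bp + params$linker_bp
  structure(states, runs = runs, class = "defect_mask")
}

.mask_codes <- function(mask) {
  match(unclass(mask), c("regular", "lh_skip", "nuc_skip")) - 1L
}

#' Grow a single chromatin fiber
#'
#' Stochastic chain growth of one E2A fiber: nucleosome repeats are laid
#' down along the genome; regular positions draw the opening angle from the
#' constrained (linker-histone) distribution, H1-skip positions from the
#' released wide distribution, and runs of nucleosome skips are replaced by
#' a discretized worm-like-chain path of naked DNA (segment length
#' `dna_seg_bp`, persistence length `naked_dna_lp_nm`). Every placement is
#' tested against the excluded volume of everything grown so far and
#' resampled on clash.
#'
#' @param config A `"e2a_sim_config"`; `n_fibers` is ignored here.
#' @param mask Optional `"defect_mask"` overriding the config's defect
#'   sampler (used for fixtures and tests).
#' @return A `"fiber_conformation"`.
#' @examples
#' cfg <- sim_config(regular_params(), fiber_length_bp = 196 * 20, seed = 7)
#' f <- grow_fiber(cfg)
#' n_nucleosomes(f)
#' @export
grow_fiber <- function(config, mask = NULL) {
  stopifnot(inherits(config, "e2a_sim_config"))
  p <- config$params
  n_rep <- floor(config$fiber_length_bp / p$nrl_bp)
  if (is.null(mask)) mask <- config$defect_sampler(p, n_rep)
  if (length(mask) != n_rep)
    stop("defect mask length must equal the number of repeats")
  restarts <- config$growth_restarts
  if (is.null(restarts)) restarts <- 0L
  for (attempt in 0:restarts) {
    ch <- cpp_grow(.mask_codes(mask), .cpp_par(p, config$growth_max_retries))
    if (isTRUE(ch$ok)) break
  }
  if (!isTRUE(ch$ok)) {
    cond <- structure(
      class = c("e2a_growth_failure", "error", "condition"),
      list(message = sprintf(
        "fiber growth failed after %d retries at %d of %d placements",
        config$growth_max_retries, ch$n_placed, n_rep),
        call = sys.call(), n_placed = ch$n_placed,
        partial_length_bp = ch$n_placed / max(1, n_rep) *
          config$fiber_length_bp))
    stop(cond)
  }
  f <- .fiber_from_chain(ch, p, config$fiber_length_bp)
  f$defect_mask <- mask
  f
}

#' Monte Carlo equilibration of a fiber
#'
#' Applies pivot moves: a chain site (nucleosome or naked-DNA joint) is
#' picked uniformly, its internal angles are resampled from the same
#' distributions used during growth, and the downstream chain is rebuilt
#' rigidly. A move is accepted iff the new conformation is free of
#' excluded-volume clashes. Because the proposal density is the target
#' (athermal) single-site distribution, acceptance on clash-freedom alone
#' satisfies detailed balance for the hard-core ensemble.
#'
#' @param fiber A `"fiber_conformation"` produced by [grow_fiber()].
#' @param config The simulation config (for retries/EV settings).
#' @param sweeps Number of sweeps; one sweep is one attempted move per chain
#'   site. `sweeps = 0` returns the fiber unchanged.
#' @return The equilibrated `"fiber_conformation"`, with attribute
#'   `mc_acceptance` (fraction of accepted moves).
#' @export
mc_equilibrate <- function(fiber, config, sweeps = config$mc_moves_per_site) {
  stopifnot(inherits(fiber, "fiber_conformation"))
  if (sweeps <= 0) return(fiber)
  p <- fiber$params
  chain <- c(fiber$elements, list())
  names(chain) <- names(fiber$elements)
  out <- cpp_mc(chain, .cpp_par(p, config$growth_max_retries),
                as.integer(sweeps))
  f <- .fiber_from_chain(out, p, fiber$genomic_length_bp)
  f$defect_mask <- fiber$defect_mask
  attr(f, "mc_acceptance") <- out$mc_accepted / max(1, out$mc_moves)
  f
}

#' Simulate an ensemble of chromatin fibers
#'
#' Generates `n_fibers` independent fibers from the configuration. Each
#' fiber gets a deterministic sub-seed derived from the ensemble seed, so
#' the ensemble is reproducible bit-for-bit and individual fibers can be
#' regenerated in isolation.
#'
#' @param config A `"e2a_sim_config"`.
#' @param progress Print a progress line every `progress` fibers; 0 for
#'   silence.
#' @return A `"fiber_ensemble"`: list with `fibers`, `config`, `seed`,
#'   `sub_seeds` and a provenance `config_hash`.
#' @examples
#' cfg <- sim_config(regular_params(), fiber_length_bp = 196 * 10,
#'                   n_fibers = 3, seed = 11)
#' ens <- simulate_ensemble(cfg)
#' length(ens$fibers)
#' @export
simulate_ensemble <- function(config, progress = 0) {
  stopifnot(inherits(config, "e2a_sim_config"))
  sub_seeds <- (config$seed + 7919 * seq_len(config$n_fibers)) %%
    .Machine$integer.max
  fibers <- vector("list", config$n_fibers)
  for (i in seq_len(config$n_fibers)) {
    set.seed(sub_seeds[i])
    fibers[[i]] <- tryCatch(
      grow_fiber(config),
      e2a_growth_failure = function(e) {
        stop(sprintf("growth failure in fiber %d: %s", i,
                     conditionMessage(e)), call. = FALSE)
      })
    if (config$mc_moves_per_site > 0)
      fibers[[i]] <- mc_equilibrate(fibers[[i]], config)
    fibers[[i]]$seed <- sub_seeds[i]
    if (progress > 0 && i %% progress == 0)
      message(sprintf("  fiber %d/%d (%d retries)", i, config$n_fibers,
                      fibers[[i]]$retries))
  }
  ens <- list(fibers = fibers, config = config, seed = config$seed,
              sub_seeds = sub_seeds,
              config_hash = config_hash(config))
  class(ens) <- "fiber_ensemble"
  ens
}

#' Provenance hash of a simulation configuration
#'
#' Order-independent numeric digest of all model and run parameters; stored
#' in ensemble archives and output file headers so that any result can be
#' traced to its exact configuration.
#'
#' @param config A `"e2a_sim_config"`.
#' @return A character scalar.
#' @export
config_hash <- function(config) {
  p <- config$params
  vals <- c(unlist(p[order(names(p))], use.names = FALSE),
            config$fiber_length_bp, config$n_fibers, config$seed,
            config$mc_moves_per_site)
  sprintf("%08x", sum(as.integer(
    (abs(as.numeric(vals)) * 1000 + seq_along(vals) * 97) %% 1e6)) %% 0xFFFFFFF)
}

#' Mean squared end-to-end distance of an ensemble
#'
#' End-to-end distance of the nucleosome-center chain (first to last placed
#' nucleosome), averaged over fibers.
#'
#' @param x A `"fiber_ensemble"` or `"fiber_conformation"`.
#' @return List with `mean_r2`, `se` (standard error over fibers) and `n`.
#' @export
end_to_end <- function(x) {
  fl <- .as_fiber_list(x)
  r2 <- vapply(fl, function(f) {
    pts <- fiber_path(f)$points
    sum((pts[nrow(pts), ] - pts[1, ])^2)
  }, numeric(1))
  list(mean_r2 = mean(r2), se = stats::sd(r2) / sqrt(length(r2)),
       n = length(r2))
}
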