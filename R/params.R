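#' Model parameters for the extended two-angle chromatin fiber
#'
#' Constructs the full parameter set of the extended two-angle (E2A) model:
#' nucleosome repeat geometry, the distributions of the opening angle
#' \eqn{\alpha} (entry--exit angle of the linker DNA at the nucleosome) and of
#' the rotational (dihedral) angle \eqn{\beta} between consecutive bend
#' planes, the DNA pitch offset between in- and outgoing strand, excluded
#' volume dimensions, and the two histone-depletion rates.
#'
#' The default angle-distribution constants and the effective
#' inter-nucleosome linker length are calibration constants, frozen by
#' [calibrate_defaults()] against the regular-fiber anchors of the model
#' (mean and spread of the nearest-neighbour nucleosome distance, the
#' mean distances at genomic separations 2 and 10 repeats, and the 280 nm
#' fiber persistence length). The shipped values are recorded in
#' `system.file("extdata", "e2a_defaults.cfg", package = "e2afiber")`.
#'
#' Note on the effective linker length: the calibrated nucleosome spacing of
#' about 51 nm is larger than 49 bp of straight B-DNA (16.7 nm). The model
#' therefore carries `linker_length_nm` as an explicit effective geometry
#' constant for nucleosome-to-nucleosome links, while naked-DNA stretches
#' left behind by nucleosome skips always use the physical rise
#' `rise_nm_per_bp`. See the package vignette for the reasoning.
#'
#' @param nrl_bp Nucleosome repeat length in bp.
#' @param wrapped_bp bp wrapped on the histone octamer.
#' @param rise_nm_per_bp B-DNA rise (nm/bp), used for naked DNA.
#' @param linker_length_nm Effective center-to-center linker length between
#'   consecutive nucleosomes (nm); calibration constant.
#' @param linker_length_sd_nm Spread of the effective linker length between
#'   repeats (nm); models nucleosome-repeat heterogeneity and is calibrated
#'   together with the angle constants.
#' @param alpha_mean,alpha_sd Mean and SD (radians) of the Gaussian opening
#'   angle distribution at positions with a linker histone.
#' @param beta_mean,beta_sd Mean and SD (radians) of the Gaussian dihedral
#'   angle distribution.
#' @param lh_alpha_range Numeric length-2: when the linker histone is missing
#'   the entry--exit constraint is released and \eqn{\alpha} is drawn
#'   uniformly from this interval (radians); the dihedral keeps its regular
#'   distribution (the H1 stem constrains the opening angle, not the linker
#'   twist).
#' @param pitch_d_nm Distance between in- and outgoing DNA strand at the
#'   nucleosome (the DNA "pitch", nm).
#' @param wrap_offset_nm Offset of the octamer center from the linker
#'   junction midpoint (nm, along the bisector of the kink).
#' @param nucleosome_radius_nm,nucleosome_height_nm Excluded-volume cylinder
#'   dimensions of the nucleosome.
#' @param dna_radius_nm Excluded-volume radius of linker/naked DNA.
#' @param p_nuc_skip Probability per repeat of a nucleosome skip (whole
#'   octamer missing, naked DNA remains).
#' @param p_lh_skip Probability per repeat of a linker-histone skip.
#' @param naked_dna_lp_nm Persistence length used for naked DNA stretches.
#' @param dna_seg_bp Discretization of naked DNA (bp per worm-like-chain
#'   segment).
#' @param contact_radius_nm Interaction radius for loop/contact detection.
#' @param analysis_cutoff_nm System size (sphere/disk radius) for the pair
#'   distribution analysis.
#'
#' @return An object of class `"e2a_params"` (named list).
#' @seealso [regular_params()], [sim_config()], [calibrate_defaults()]
#' @examples
#' p <- e2a_params()
#' p$nrl_bp
#' # parameters of an undisturbed ("regular") fiber
#' regular_params()$p_nuc_skip
#' @export
e2a_params <- function(nrl_bp = 196L,
                       wrapped_bp = 147L,
                       rise_nm_per_bp = 0.34,
                       linker_length_nm = .e2a_cal$linker_length_nm,
                       linker_length_sd_nm = .e2a_cal$linker_length_sd_nm,
                       alpha_mean = .e2a_cal$alpha_mean,
                       alpha_sd = .e2a_cal$alpha_sd,
                       beta_mean = .e2a_cal$beta_mean,
                       beta_sd = .e2a_cal$beta_sd,
                       lh_alpha_range = .e2a_cal$lh_alpha_range,
                       pitch_d_nm = 2.7,
                       wrap_offset_nm = 4.2,
                       nucleosome_radius_nm = 5.5,
                       nucleosome_height_nm = 5.5,
                       dna_radius_nm = 1.2,
                       p_nuc_skip = 0.08,
                       p_lh_skip = 0.06,
                       naked_dna_lp_nm = 50,
                       dna_seg_bp = 10,
                       contact_radius_nm = 35,
                       analysis_cutoff_nm = 40) {
  p <- list(
    nrl_bp = as.integer(nrl_bp), wrapped_bp = as.integer(wrapped_bp),
    linker_bp = as.integer(nrl_bp) - as.integer(wrapped_bp),
    rise_nm_per_bp = rise_nm_per_bp, linker_length_nm = linker_length_nm,
    linker_length_sd_nm = linker_length_sd_nm,
    alpha_mean = alpha_mean, alpha_sd = alpha_sd,
    beta_mean = beta_mean, beta_sd = beta_sd,
    lh_alpha_range = lh_alpha_range,
    pitch_d_nm = pitch_d_nm, wrap_offset_nm = wrap_offset_nm,
    nucleosome_radius_nm = nucleosome_radius_nm,
    nucleosome_height_nm = nucleosome_height_nm,
    dna_radius_nm = dna_radius_nm,
    p_nuc_skip = p_nuc_skip, p_lh_skip = p_lh_skip,
    naked_dna_lp_nm = naked_dna_lp_nm, dna_seg_bp = dna_seg_bp,
    contact_radius_nm = contact_radius_nm,
    analysis_cutoff_nm = analysis_cutoff_nm
  )
  class(p) <- "e2a_params"
  validate_e2a_params(p)
  p
}

#' Parameters of an undisturbed (regular) chromatin fiber
#'
#' Convenience wrapper around [e2a_params()] with both histone-depletion
#' rates set to zero.
#'
#' @param ... Passed on to [e2a_params()].
#' @return An `"e2a_params"` object with `p_nuc_skip = p_lh_skip = 0`.
#' @export
regular_params <- function(...) {
  e2a_params(p_nuc_skip = 0, p_lh_skip = 0, ...)
}

#' Validate an e2a_params object
#'
#' Checks the structural invariants of the parameter set: rates in
#' \eqn{[0,1]}, positive lengths, wrapped DNA shorter than the repeat, a
#' proper opening-angle interval for linker-histone skips.
#'
#' @param p An `"e2a_params"` object.
#' @return `p`, invisibly. Throws an error describing the first violated
#'   invariant otherwise.
#' @export
validate_e2a_params <- function(p) {
  stopifnot(inherits(p, "e2a_params"))
  if (p$p_nuc_skip < 0 || p$p_nuc_skip > 1 ||
      p$p_lh_skip < 0 || p$p_lh_skip > 1)
    stop("skip rates must lie in [0, 1]")
  len_fields <- c("rise_nm_per_bp", "linker_length_nm", "pitch_d_nm",
                  "nucleosome_radius_nm", "nucleosome_height_nm",
                  "dna_radius_nm", "naked_dna_lp_nm", "dna_seg_bp",
                  "contact_radius_nm", "analysis_cutoff_nm")
  for (f in len_fields)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] <= 0)
      stop("parameter '", f, "' must be a positive length")
  if (p$wrapped_bp >= p$nrl_bp)
    stop("wrapped_bp must be smaller than nrl_bp")
  if (p$wrap_offset_nm < 0) stop("wrap_offset_nm must be non-negative")
  if (length(p$lh_alpha_range) != 2L ||
      p$lh_alpha_range[1] >= p$lh_alpha_range[2] ||
      p$lh_alpha_range[1] < 0 || p$lh_alpha_range[2] > pi)
    stop("lh_alpha_range must be an increasing interval inside [0, pi]")
  if (p$alpha_mean <= 0 || p$alpha_mean >= pi)
    stop("alpha_mean must lie in (0, pi)")
  if (p$alpha_sd < 0 || p$beta_sd < 0) stop("angle SDs must be >= 0")
  if (p$linker_length_sd_nm < 0) stop("linker_length_sd_nm must be >= 0")
  invisible(p)
}

#' @export
print.e2a_params <- function(x, ...) {
  cat("Extended two-angle model parameters\n")
  cat(sprintf("  NRL %d bp (%d wrapped + %d linker), effective linker %.2f nm\n",
              x$nrl_bp, x$wrapped_bp, x$linker_bp, x$linker_length_nm))
  cat(sprintf("  alpha ~ N(%.4f, %.4f) rad, beta ~ N(%.4f, %.4f) rad\n",
              x$alpha_mean, x$alpha_sd, x$beta_mean, x$beta_sd))
  cat(sprintf("  H1 skip: alpha ~ U(%.3f, %.3f), rate %.2f; nucleosome skip rate %.2f\n",
              x$lh_alpha_range[1], x$lh_alpha_range[2], x$p_lh_skip,
              x$p_nuc_skip))
  cat(sprintf("  pitch %.2f nm, wrap offset %.2f nm, naked DNA lp %.1f nm\n",
              x$pitch_d_nm, x$wrap_offset_nm, x$naked_dna_lp_nm))
  cat(sprintf("  contact radius %.1f nm, analysis cutoff %.1f nm\n",
              x$contact_radius_nm, x$analysis_cutoff_nm))
  invisible(x)
}

# flat parameter list handed to the C++ core
.cpp_par <- function(p, max_retries = 100L, use_ev = TRUE) {
  list(alpha_mean = p$alpha_mean, alpha_sd = p$alpha_sd,
       beta_mean = p$beta_mean, beta_sd = p$beta_sd,
       lh_alpha_min = p$lh_alpha_range[1], lh_alpha_max = p$lh_alpha_range[2],
       linker_nm = p$linker_length_nm, linker_sd = p$linker_length_sd_nm,
       pitch_nm = p$pitch_d_nm,
       wrap_off = p$wrap_offset_nm, nrl_bp = as.numeric(p$nrl_bp),
       linker_bp = as.numeric(p$linker_bp), rise = p$rise_nm_per_bp,
       seg_bp = p$dna_seg_bp, naked_lp = p$naked_dna_lp_nm,
       sub_r = p$nucleosome_height_nm / 2,
       ring_r = p$nucleosome_radius_nm - p$nucleosome_height_nm / 2,
       dna_r = p$dna_radius_nm, excl_bp = as.numeric(p$nrl_bp),
       max_retries = as.integer(max_retries), use_ev = isTRUE(use_ev))
}
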