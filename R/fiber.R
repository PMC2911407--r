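# fiber_conformation and fiber_ensemble classes

.fiber_from_chain <- function(chain, params, genomic_length_bp, seed = NA) {
  n <- nrow(chain$centers)
  # place the first nucleosome center at the origin (or the first DNA vertex
  # for all-naked fibers)
  origin <- if (n > 0) chain$centers[1, ] else chain$dna[1, ]
  shift <- function(m) if (nrow(m) > 0) sweep(m, 2, origin) else m
  f <- list(
    centers = shift(chain$centers),
    entry = shift(chain$entry),
    exit = shift(chain$exit),
    axis = chain$axis,
    tin = chain$tin,
    genomic_index = as.integer(chain$gidx),
    nucleosome_bp = as.numeric(chain$nuc_bp),
    lh_skip = as.logical(chain$lh_skip),
    alpha = as.numeric(chain$alpha),
    beta = as.numeric(chain$beta),
    dna_path = shift(chain$dna),
    dna_bp = as.numeric(chain$dna_bp),
    elements = chain[c("el_type", "el_sub", "el_gidx", "el_len",
                       "el_a1", "el_a2", "el_bp")],
    defect_mask = NULL,
    genomic_length_bp = genomic_length_bp,
    params = params,
    seed = seed,
    retries = chain$retries
  )
  class(f) <- "fiber_conformation"
  f
}

#' Number of nucleosomes in a fiber
#' @param fiber A `"fiber_conformation"`.
#' @return Integer count of placed nucleosomes.
#' @export
n_nucleosomes <- function(fiber) nrow(fiber$centers)

#' @export
print.fiber_conformation <- function(x, ...) {
  cat(sprintf("Chromatin fiber conformation: %d nucleosomes, %.1f kbp\n",
              n_nucleosomes(x), x$genomic_length_bp / 1000))
  if (!is.null(x$defect_mask)) {
    tb <- table(factor(x$defect_mask, levels = c("regular", "lh_skip",
                                                 "nuc_skip")))
    cat(sprintf("  defects: %d regular, %d H1 skips, %d nucleosome skips\n",
                tb[["regular"]], tb[["lh_skip"]], tb[["nuc_skip"]]))
  }
  if (nrow(x$dna_path) > 0)
    cat(sprintf("  naked DNA path: %d vertices\n", nrow(x$dna_path)))
  invisible(x)
}

#' Validate the structural invariants of a fiber conformation
#'
#' Checks that genomic indices are strictly increasing, that index gaps
#' correspond exactly to nucleosome-skip runs of the defect mask (when
#' present), and that no two nucleosome centers lie closer than the
#' excluded-volume contact distance (the nucleosome cylinder height, i.e.
#' the face-to-face stacking distance of the sphere decomposition).
#'
#' @param fiber A `"fiber_conformation"`.
#' @param check_ev Also audit the excluded volume with the brute-force
#'   oracle ([audit_excluded_volume()]); quadratic cost, meant for tests.
#' @return `fiber`, invisibly; errors on the first violated invariant.
#' @export
validate_fiber <- function(fiber, check_ev = FALSE) {
  stopifnot(inherits(fiber, "fiber_conformation"))
  gi <- fiber$genomic_index
  if (length(gi) > 1 && any(diff(gi) < 1))
    stop("genomic indices must increase by at least 1")
  if (!is.null(fiber$defect_mask)) {
    present <- which(fiber$defect_mask != "nuc_skip") - 1L
    if (!identical(as.integer(present), as.integer(gi)))
      stop("genomic index gaps do not match the nucleosome-skip runs")
  }
  n <- n_nucleosomes(fiber)
  if (n > 1) {
    dmin <- min(stats::dist(fiber$centers))
    contact <- fiber$params$nucleosome_height_nm
    if (dmin < contact - 1e-9)
      stop(sprintf("nucleosome centers %.3f nm apart (< contact %.3f nm)",
                   dmin, contact))
  }
  if (check_ev) {
    aud <- audit_excluded_volume(fiber)
    if (aud$overlap) stop("excluded-volume overlap detected by audit")
  }
  invisible(fiber)
}

#' @export
print.fiber_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d chromatin fibers (%.1f kbp each), seed %s\n",
              length(x$fibers), x$config$fiber_length_bp / 1000,
              format(x$seed)))
  cat(sprintf("  skip rates: nucleosome %.2f, linker histone %.2f\n",
              x$config$params$p_nuc_skip, x$config$params$p_lh_skip))
  invisible(x)
}

#' Extract all fiber path points with genomic coordinates
#'
#' The fiber path used for contact analysis: nucleosome centers plus the
#' vertices of naked-DNA stretches, each carrying its genomic coordinate in
#' bp. Regular linker DNA is represented by its endpoints (the nucleosome
#' sites) only.
#'
#' @param fiber A `"fiber_conformation"`.
#' @param sites `"all"` (nucleosomes + naked DNA vertices) or
#'   `"nucleosomes"`.
#' @return A list with `points` (matrix, nm) and `bp` (numeric vector),
#'   ordered along the genome.
#' @export
fiber_path <- function(fiber, sites = c("all", "nucleosomes")) {
  sites <- match.arg(sites)
  pts <- fiber$centers
  bp <- fiber$nucleosome_bp
  if (sites == "all" && nrow(fiber$dna_path) > 0) {
    pts <- rbind(pts, fiber$dna_path)
    bp <- c(bp, fiber$dna_bp)
  }
  o <- order(bp)
  list(points = pts[o, , drop = FALSE], bp = bp[o])
}

# iterate over fibers of an ensemble or a single fiber uniformly
.as_fiber_list <- function(x) {
  if (inherits(x, "fiber_ensemble")) return(x$fibers)
  if (inherits(x, "fiber_conformation")) return(list(x))
  stop("expected a fiber_conformation or fiber_ensemble")
}
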