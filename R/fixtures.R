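# Deterministic small conformations with analytically known properties,
# and the brute-force pair oracle used throughout the test suite.

#' Deterministic fixture conformations
#'
#' Small fibers with analytically known pair-distance multisets, contact
#' sets and stiffness, used as oracles:
#' \describe{
#'   \item{rod}{collinear nucleosomes at fixed spacing; pair distances are
#'     exact multiples of the spacing.}
#'   \item{helix}{regular helix with given radius, rise and turn per step.}
#'   \item{hairpin}{two antiparallel straight arms joined by a turn, with a
#'     prescribed tip-to-tip closure distance across the fold.}
#'   \item{random_gas}{uniform points in a sphere of the analysis radius
#'     (ideal-gas reference: g(r) close to 1).}
#' }
#'
#' @param kind One of `"rod"`, `"helix"`, `"hairpin"`, `"random_gas"`.
#' @param n Number of nucleosomes.
#' @param seed RNG seed (only `random_gas` draws random numbers).
#' @param spacing_nm Site spacing (rod, hairpin arms).
#' @param radius_nm Helix radius or gas sphere radius.
#' @param rise_nm,phi Helix rise and turn per step.
#' @param tip_gap_nm Hairpin tip closure distance.
#' @param params Model parameters attached to the fixture.
#' @return A `"fiber_conformation"` with consecutive genomic indices.
#' @export
fixture_fiber <- function(kind = c("rod", "helix", "hairpin", "random_gas"),
                          n = 10, seed = 1, spacing_nm = 20,
                          radius_nm = 40, rise_nm = 10, phi = pi / 3,
                          tip_gap_nm = 30, params = e2a_params()) {
  kind <- match.arg(kind)
  centers <- switch(kind,
    rod = cbind(0, 0, (seq_len(n) - 1) * spacing_nm),
    helix = cbind(radius_nm * cos((seq_len(n) - 1) * phi),
                  radius_nm * sin((seq_len(n) - 1) * phi),
                  (seq_len(n) - 1) * rise_nm),
    hairpin = {
      half <- ceiling(n / 2)
      up <- cbind(0, 0, (seq_len(half) - 1) * spacing_nm)
      down <- cbind(tip_gap_nm, 0,
                    rev((seq_len(n - half) - 1) * spacing_nm) +
                      (half - (n - half)) * spacing_nm)
      rbind(up, down)
    },
    random_gas = {
      set.seed(seed)
      m <- matrix(stats::rnorm(3 * 4 * n), ncol = 3)
      m <- m / sqrt(rowSums(m^2)) * radius_nm * stats::runif(4 * n)^(1 / 3)
      m[seq_len(n), , drop = FALSE]
    })
  n <- nrow(centers)
  f <- list(centers = centers,
            entry = centers, exit = centers,
            axis = matrix(rep(c(0, 0, 1), n), ncol = 3, byrow = TRUE),
            tin = matrix(rep(c(1, 0, 0), n), ncol = 3, byrow = TRUE),
            genomic_index = seq_len(n) - 1L,
            nucleosome_bp = (seq_len(n) - 1) * params$nrl_bp +
              params$linker_bp + (params$nrl_bp - params$linker_bp) / 2,
            lh_skip = rep(FALSE, n),
            alpha = rep(NA_real_, n), beta = rep(NA_real_, n),
            dna_path = matrix(numeric(0), 0, 3), dna_bp = numeric(0),
            elements = list(el_type = integer(0), el_sub = integer(0),
                            el_gidx = integer(0), el_len = numeric(0),
                            el_a1 = numeric(0), el_a2 = numeric(0),
                            el_bp = numeric(0)),
            defect_mask = NULL,
            genomic_length_bp = n * params$nrl_bp,
            params = params, seed = seed, retries = 0)
  class(f) <- "fiber_conformation"
  f
}

#' Brute-force pair distances
#'
#' Plain O(N^2) pair-distance multiset with no spatial acceleration; the
#' independent oracle against which the histogram and contact code is
#' tested.
#'
#' @param points Matrix of points (2 or 3 columns).
#' @param cutoff_nm Keep pairs with distance at or below this cutoff.
#' @return Sorted numeric vector of pair distances.
#' @export
brute_force_pairs <- function(points, cutoff_nm = Inf) {
  d <- as.numeric(stats::dist(as.matrix(points)))
  sort(d[d <= cutoff_nm])
}
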