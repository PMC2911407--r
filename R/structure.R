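# Structural observables: pair distances, conditional probability p(r),
# r_Delta statistics, g(r) in 3D and 2D, scattering function, projections,
# peak detection and allocation.

.point_sets <- function(x) {
  # -> list of list(points = matrix, gidx = integer or NULL)
  if (inherits(x, "fiber_ensemble"))
    return(lapply(x$fibers, function(f)
      list(points = f$centers, gidx = f$genomic_index)))
  if (inherits(x, "fiber_conformation"))
    return(list(list(points = x$centers, gidx = x$genomic_index)))
  if (inherits(x, "projected_ensemble"))
    return(lapply(x$fibers, function(f)
      list(points = f$points, gidx = f$genomic_index)))
  if (inherits(x, "projected_fiber"))
    return(list(list(points = x$points, gidx = x$genomic_index)))
  if (is.matrix(x))
    return(list(list(points = x, gidx = NULL)))
  if (is.list(x) && all(vapply(x, is.matrix, logical(1))))
    return(lapply(x, function(m) list(points = m, gidx = NULL)))
  stop("cannot interpret input as nucleosome point sets")
}

#' Stream nucleosome pair distances with their genomic separation
#'
#' All unordered nucleosome pairs of each fiber with spatial distance
#' `r <= cutoff_nm`, labelled by the genomic separation
#' \eqn{\Delta} in repeat (NRL) units computed from the genomic indices.
#' Skipped nucleosomes leave index gaps, so a pair flanking a skip run
#' appears at its true genomic separation.
#'
#' @param x Fiber, ensemble, or matrix of labelled points.
#' @param cutoff_nm Spatial cutoff (nm); `Inf` keeps every pair.
#' @param delta_max Largest genomic separation streamed; `Inf` for all.
#' @param delta_units `"genomic"` (default): \eqn{\Delta} is the difference
#'   of genomic indices, so pairs flanking a nucleosome-skip run appear at
#'   their true repeat separation and \eqn{\Delta = 1} holds only for
#'   genomically adjacent nucleosomes. `"ordinal"`: \eqn{\Delta} counts
#'   placed nucleosomes, so the \eqn{\Delta = 1} average runs over skip-
#'   flanking neighbour pairs as well — the averaging convention used for
#'   disturbed-fiber distance tables.
#' @return Data frame with columns `delta` (integer, NRL units) and `r`
#'   (nm).
#' @export
pair_distances <- function(x, cutoff_nm = Inf, delta_max = Inf,
                           delta_units = c("genomic", "ordinal")) {
  if (cutoff_nm <= 0) stop("cutoff_nm must be > 0")
  delta_units <- match.arg(delta_units)
  sets <- .point_sets(x)
  out <- vector("list", length(sets))
  for (s in seq_along(sets)) {
    pts <- sets[[s]]$points
    gi <- sets[[s]]$gidx
    if (is.null(gi) || delta_units == "ordinal")
      gi <- seq_len(nrow(pts)) - 1L
    dmax <- if (is.finite(delta_max)) delta_max else diff(range(gi))
    res <- vector("list", dmax)
    for (d in seq_len(dmax)) {
      j <- match(gi + d, gi)
      keep <- !is.na(j)
      if (!any(keep)) next
      i <- which(keep)
      r <- sqrt(rowSums((pts[j[i], , drop = FALSE] -
                           pts[i, , drop = FALSE])^2))
      r <- r[r <= cutoff_nm]
      if (length(r)) res[[d]] <- data.frame(delta = d, r = r)
    }
    out[[s]] <- do.call(rbind, res)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(delta = integer(), r = numeric())
  res
}

#' Conditional probability histogram of nucleosome pair distances
#'
#' Histogram of all unordered pair distances up to the analysis cutoff.
#' This is the discrete estimate of the conditional probability p(r) of
#' finding a nucleosome at distance r from a reference nucleosome.
#'
#' @param x Fiber, ensemble, projected fiber/ensemble, or point matrix
#'   (2 or 3 columns).
#' @param bin_width_nm Histogram bin (nm); the analysis default is 0.2 nm.
#' @param cutoff_nm System size R (nm); `Inf` extends the histogram to the
#'   largest observed distance.
#' @return A `"distance_histogram"`: list with `breaks`, `mids`, `counts`,
#'   `n_pairs_total`, `n_pairs_within`, `n_points_total`, `n_sets`,
#'   `dimension`, `cutoff_nm`, `bin_width_nm`.
#' @seealso [as_probability()], [pair_distribution_3d()],
#'   [pair_distribution_2d()]
#' @export
conditional_probability <- function(x, bin_width_nm = 0.2, cutoff_nm = 40) {
  sets <- .point_sets(x)
  dim0 <- ncol(sets[[1]]$points)
  counts <- NULL
  n_pairs_total <- 0; n_within <- 0; n_points <- 0
  cut_used <- cutoff_nm
  if (!is.finite(cutoff_nm)) {
    # global maximum distance so all sets share one binning
    dmax <- max(vapply(sets, function(s) {
      h <- cpp_pair_hist(s$points, -1, bin_width_nm)
      h$cutoff
    }, numeric(1)))
    cut_used <- dmax
  }
  nb <- max(1L, ceiling(cut_used / bin_width_nm))
  counts <- numeric(nb)
  for (s in sets) {
    h <- cpp_pair_hist(s$points, cut_used, bin_width_nm)
    counts[seq_along(h$counts)] <- counts[seq_along(h$counts)] + h$counts
    n_pairs_total <- n_pairs_total + h$n_pairs_total
    n_within <- n_within + h$n_pairs_within
    n_points <- n_points + h$n_points
  }
  breaks <- seq(0, by = bin_width_nm, length.out = nb + 1)
  out <- list(breaks = breaks, mids = (breaks[-1] + breaks[-(nb + 1)]) / 2,
              counts = counts, n_pairs_total = n_pairs_total,
              n_pairs_within = n_within, n_points_total = n_points,
              n_sets = length(sets), dimension = dim0,
              cutoff_nm = cut_used, bin_width_nm = bin_width_nm)
  class(out) <- "distance_histogram"
  out
}

#' @export
print.distance_histogram <- function(x, ...) {
  cat(sprintf("%dD pair-distance histogram: %d bins of %.3g nm up to %.4g nm\n",
              x$dimension, length(x$counts), x$bin_width_nm, x$cutoff_nm))
  cat(sprintf("  %s of %s pairs within cutoff (%d point sets)\n",
              format(x$n_pairs_within, big.mark = ","),
              format(x$n_pairs_total, big.mark = ","), x$n_sets))
  invisible(x)
}

#' Normalized p(r) series from a distance histogram
#'
#' Two normalization conventions are provided. `"unit_mass"` (default)
#' normalizes p(r) to unit integral over `[0, cutoff]`, which makes curve
#' shapes comparable across ensembles. `"all_pairs"` divides by the total
#' pair count, so that `sum(p * bin)` equals the fraction of pairs with
#' `r <= cutoff`.
#'
#' @param hist A `"distance_histogram"`.
#' @param normalization `"unit_mass"` or `"all_pairs"`.
#' @return Data frame with `r` (bin centers, nm) and `p` (1/nm), carrying
#'   the source histogram as attribute `histogram`.
#' @export
as_probability <- function(hist,
                           normalization = c("unit_mass", "all_pairs")) {
  normalization <- match.arg(normalization)
  denom <- switch(normalization,
                  unit_mass = max(1, hist$n_pairs_within),
                  all_pairs = max(1, hist$n_pairs_total))
  p <- hist$counts / (denom * hist$bin_width_nm)
  out <- data.frame(r = hist$mids, p = p)
  attr(out, "histogram") <- hist
  attr(out, "normalization") <- normalization
  out
}

#' Per-genomic-separation distance statistics
#'
#' For each genomic separation \eqn{\Delta = 1..\Delta_{max}} (NRL units):
#' the mean spatial distance, its standard deviation, the most frequent
#' value (histogram mode at `mode_bin_nm` resolution, ties broken toward
#' smaller r) and the sample count.
#'
#' @param x Fiber/ensemble, or a data frame from [pair_distances()].
#' @param delta_max Largest separation tabulated.
#' @param mode_bin_nm Bin width for the mode estimate.
#' @param delta_units Separation convention, see [pair_distances()];
#'   `"ordinal"` reproduces the disturbed-fiber convention in which the
#'   \eqn{\Delta = 1} row averages over skip-flanking pairs too.
#' @return Data frame of class `"rdelta_stats"` with columns `delta`,
#'   `mean`, `sd`, `mode`, `n`.
#' @export
r_delta_stats <- function(x, delta_max = 10, mode_bin_nm = 0.2,
                          delta_units = c("genomic", "ordinal")) {
  pd <- if (is.data.frame(x)) x else
    pair_distances(x, cutoff_nm = Inf, delta_max = delta_max,
                   delta_units = match.arg(delta_units))
  pd <- pd[pd$delta <= delta_max, ]
  out <- data.frame(delta = seq_len(delta_max), mean = NA_real_,
                    sd = NA_real_, mode = NA_real_, n = 0L)
  for (d in seq_len(delta_max)) {
    r <- pd$r[pd$delta == d]
    if (!length(r)) next
    out$mean[d] <- mean(r)
    out$sd[d] <- if (length(r) > 1) stats::sd(r) else 0
    b <- floor(r / mode_bin_nm)
    tb <- table(b)
    top <- as.numeric(names(tb)[tb == max(tb)])
    out$mode[d] <- (min(top) + 0.5) * mode_bin_nm
    out$n[d] <- length(r)
  }
  class(out) <- c("rdelta_stats", "data.frame")
  out
}

#' Radial pair distribution function g(r) in 3D
#'
#' Normalizes the pair-distance histogram so that a value of one equals the
#' mean nucleosome density of the bounded system, a sphere of the cutoff
#' radius around each reference nucleosome:
#' \deqn{g(r) = \frac{n(r)}{4 \pi r^2 \Delta r \, \bar\rho}}
#' with n(r) the mean per-reference shell count and \eqn{\bar\rho} the mean
#' per-reference density inside the R-sphere. Bins are evaluated at their
#' centers; a literal r = 0 self term is never present since pairs are
#' distinct.
#'
#' @param hist A 3D `"distance_histogram"` with finite cutoff.
#' @return Data frame with `r`, `g`; attributes `rho` (mean density,
#'   nm^-3) and `histogram`.
#' @export
pair_distribution_3d <- function(hist) {
  stopifnot(inherits(hist, "distance_histogram"))
  if (hist$dimension != 3) stop("3D histogram required")
  if (!is.finite(hist$cutoff_nm)) stop("finite cutoff required")
  per_ref <- 2 * hist$counts / max(1, hist$n_points_total)
  rho <- (2 * hist$n_pairs_within / max(1, hist$n_points_total)) /
    (4 / 3 * pi * hist$cutoff_nm^3)
  g <- per_ref / (4 * pi * hist$mids^2 * hist$bin_width_nm * rho)
  out <- data.frame(r = hist$mids, g = g)
  attr(out, "rho") <- rho
  attr(out, "histogram") <- hist
  out
}

#' Radial pair distribution function g2D(r) after projection
#'
#' Two-dimensional analogue of [pair_distribution_3d()]: shell counts are
#' normalized by ring areas and the mean areal density inside the R-disk,
#' \deqn{g_{2D}(r) = \frac{n(r)}{2 \pi r \Delta r \, \bar\rho_{2D}}.}
#'
#' @param hist A 2D `"distance_histogram"` with finite cutoff (from
#'   projected fibers).
#' @return Data frame with `r`, `g`; attributes `rho` (areal density,
#'   nm^-2) and `histogram`.
#' @export
pair_distribution_2d <- function(hist) {
  stopifnot(inherits(hist, "distance_histogram"))
  if (hist$dimension != 2) stop("2D histogram required")
  if (!is.finite(hist$cutoff_nm)) stop("finite cutoff required")
  per_ref <- 2 * hist$counts / max(1, hist$n_points_total)
  rho <- (2 * hist$n_pairs_within / max(1, hist$n_points_total)) /
    (pi * hist$cutoff_nm^2)
  g <- per_ref / (2 * pi * hist$mids * hist$bin_width_nm * rho)
  out <- data.frame(r = hist$mids, g = g)
  attr(out, "rho") <- rho
  attr(out, "histogram") <- hist
  out
}

#' Isotropic scattering function S(q)
#'
#' Fourier transform of the pair correlation g(r) - 1 for an isotropic
#' system, by trapezoidal quadrature over the bounded analysis volume:
#' \deqn{S(q) = 1 + 4 \pi \bar\rho \int_0^R (g(r) - 1)\, r^2\,
#'   \frac{\sin qr}{qr}\, dr.}
#'
#' @param g_series Output of [pair_distribution_3d()].
#' @param q Wave numbers (1/nm).
#' @return Data frame of class `"scattering_function"` with `q`, `S`.
#' @export
scattering_function <- function(g_series,
                                q = seq(0.05, 3, length.out = 300)) {
  rho <- attr(g_series, "rho")
  if (is.null(rho)) stop("g_series must come from pair_distribution_3d()")
  r <- g_series$r
  h <- g_series$g - 1
  dr <- diff(r)
  S <- vapply(q, function(qq) {
    sinc <- ifelse(qq * r < 1e-12, 1, sin(qq * r) / (qq * r))
    f <- h * r^2 * sinc
    1 + 4 * pi * rho * sum((f[-1] + f[-length(f)]) / 2 * dr)
  }, numeric(1))
  out <- data.frame(q = q, S = S)
  class(out) <- c("scattering_function", "data.frame")
  out
}

#' Project fibers onto a plane
#'
#' Orthogonal projection of nucleosome centers onto the plane normal to a
#' given axis, as in 2D localization microscopy. Pair distances can only
#' shrink under projection.
#'
#' @param x A fiber or ensemble.
#' @param axis Numeric length-3 projection axis, or `"random"` for an
#'   independent uniformly distributed axis per fiber (drawn from the
#'   current RNG stream).
#' @return A `"projected_fiber"` (list with `points` n x 2,
#'   `genomic_index`, `axis`) or a `"projected_ensemble"` of them.
#' @export
project_fiber <- function(x, axis = c(0, 0, 1)) {
  project_one <- function(f) {
    ax <- if (identical(axis, "random")) .random_axis() else .unit(axis)
    e <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    b1 <- .unit(e - sum(e * ax) * ax)
    b2 <- c(ax[2] * b1[3] - ax[3] * b1[2], ax[3] * b1[1] - ax[1] * b1[3],
            ax[1] * b1[2] - ax[2] * b1[1])
    pts <- if (inherits(f, "fiber_conformation")) f$centers else f
    gi <- if (inherits(f, "fiber_conformation")) f$genomic_index else NULL
    out <- list(points = cbind(as.numeric(pts %*% b1),
                               as.numeric(pts %*% b2)),
                genomic_index = gi, axis = ax)
    class(out) <- "projected_fiber"
    out
  }
  if (inherits(x, "fiber_ensemble")) {
    out <- list(fibers = lapply(x$fibers, project_one))
    class(out) <- "projected_ensemble"
    return(out)
  }
  project_one(x)
}

.random_axis <- function() {
  z <- stats::runif(1, -1, 1)
  ph <- stats::runif(1, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  c(s * cos(ph), s * sin(ph), z)
}

#' Detect peaks of p(r) and allocate genomic separations
#'
#' Finds local maxima of the (lightly smoothed) pair-distance probability
#' above a prominence threshold, bounds each peak by the minima towards its
#' neighbours, and — when per-separation statistics are supplied — assigns
#' to each peak the genomic separations whose most-frequent value falls
#' inside the peak's support.
#'
#' @param p_series Data frame with `r` and `p` (e.g. [as_probability()]).
#' @param components Optional `"rdelta_stats"` used for the allocation.
#' @param min_prominence_frac Peaks whose topographic prominence (height
#'   above the highest saddle towards a higher peak) is below this fraction
#'   of the global height range are discarded.
#' @param smooth_bins Running-median window (bins) applied before detection.
#' @return A `"peak_allocation"`: data frame with `peak`, `position_nm`,
#'   `height`, `left_nm`, `right_nm` and a list column `delta` of assigned
#'   separations (empty when `components` is `NULL`). Flat input yields
#'   zero rows.
#' @export
detect_peaks <- function(p_series, components = NULL,
                         min_prominence_frac = 0.02, smooth_bins = 5) {
  r <- p_series$r
  p <- p_series$p
  if (smooth_bins > 1)
    p <- stats::runmed(p, k = smooth_bins - (1 - smooth_bins %% 2))
  n <- length(p)
  out0 <- data.frame(peak = integer(), position_nm = numeric(),
                     height = numeric(), left_nm = numeric(),
                     right_nm = numeric())
  out0$delta <- list()
  class(out0) <- c("peak_allocation", "data.frame")
  if (n < 3 || max(p) <= 0 || diff(range(p)) == 0) return(out0)
  cand <- which(p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] >= p[3:n]) + 1L
  if (!length(cand)) return(out0)
  # topographic prominence: drop to the highest saddle towards a higher
  # point on either side (boundaries count as open ends)
  prom <- vapply(cand, function(i) {
    lmin <- p[i]; j <- i
    while (j > 1 && p[j] <= p[i]) {
      lmin <- min(lmin, p[j]); j <- j - 1
    }
    left <- if (p[j] > p[i]) lmin else min(p[1:i])
    rmin <- p[i]; j <- i
    while (j < n && p[j] <= p[i]) {
      rmin <- min(rmin, p[j]); j <- j + 1
    }
    right <- if (p[j] > p[i]) rmin else min(p[i:n])
    p[i] - max(left, right)
  }, numeric(1))
  keep <- cand[prom >= min_prominence_frac * diff(range(p))]
  if (!length(keep)) return(out0)
  bounds_l <- numeric(length(keep)); bounds_r <- numeric(length(keep))
  for (k in seq_along(keep)) {
    lo <- if (k == 1) 1L else keep[k - 1] +
      which.min(p[keep[k - 1]:keep[k]]) - 1L
    hi <- if (k == length(keep)) n else keep[k] +
      which.min(p[keep[k]:keep[k + 1]]) - 1L
    bounds_l[k] <- r[lo]; bounds_r[k] <- r[hi]
  }
  out <- data.frame(peak = seq_along(keep), position_nm = r[keep],
                    height = p[keep], left_nm = bounds_l,
                    right_nm = bounds_r)
  out$delta <- lapply(seq_along(keep), function(k) {
    if (is.null(components)) return(integer())
    ok <- !is.na(components$mode) & components$mode >= bounds_l[k] &
      components$mode <= bounds_r[k]
    as.integer(components$delta[ok])
  })
  class(out) <- c("peak_allocation", "data.frame")
  out
}

#' @export
print.peak_allocation <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("No peaks detected\n")
    return(invisible(x))
  }
  cat("Detected p(r) peaks:\n")
  for (k in seq_len(nrow(x))) {
    dl <- x$delta[[k]]
    cat(sprintf("  %2d at %6.2f nm [%.2f, %.2f]  Delta = {%s}\n",
                x$peak[k], x$position_nm[k], x$left_nm[k], x$right_nm[k],
                if (length(dl)) paste(dl, collapse = ",") else "-"))
  }
  invisible(x)
}
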