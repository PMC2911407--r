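# Deterministic local geometry of the extended two-angle step.

.unit <- function(v) v / sqrt(sum(v^2))

#' Construct a nucleosome frame
#'
#' A frame describes the state of the growing chain at a nucleosome exit:
#' the current chain end `origin`, the outgoing linker direction `t` and a
#' normal reference `n` (unit, orthogonal to `t`) that anchors the dihedral
#' angle of the next step.
#'
#' @param origin Numeric length-3, chain end position (nm).
#' @param t Outgoing tangent (unit vector).
#' @param n Normal reference (unit vector orthogonal to `t`).
#' @return An object of class `"nucleosome_frame"`.
#' @export
nucleosome_frame <- function(origin = c(0, 0, 0), t = c(0, 0, 1),
                             n = c(1, 0, 0)) {
  t <- as.numeric(t); n <- as.numeric(n); origin <- as.numeric(origin)
  f <- list(origin = origin, t = t, n = n)
  class(f) <- "nucleosome_frame"
  validate_frame(f)
  f
}

validate_frame <- function(f, tol = 1e-8) {
  if (abs(sum(f$t^2) - 1) > tol || abs(sum(f$n^2) - 1) > tol ||
      abs(sum(f$t * f$n)) > tol)
    stop("frame is not orthonormal: t and n must be orthogonal unit vectors")
  invisible(f)
}

#' One deterministic step of the extended two-angle model
#'
#' Given the frame at the previous nucleosome exit, places the next
#' nucleosome: the incoming and outgoing linker subtend the opening angle
#' `alpha` at the nucleosome, the bend plane is rotated by the dihedral
#' `beta` about the incoming linker, the entry and exit points differ by the
#' DNA pitch along the nucleosome axis, and the octamer center sits on the
#' inside of the kink at the wrap offset. Fully deterministic and
#' frame-covariant: rotating the input frame rotates the output identically.
#'
#' @param frame A `"nucleosome_frame"` (see [nucleosome_frame()]).
#' @param alpha Opening angle (radians, in (0, pi]); `alpha = pi` is a
#'   straight pass-through.
#' @param beta Dihedral angle (radians).
#' @param linker_length_nm Length of the incoming linker (nm, > 0).
#' @param pitch_d_nm Entry-to-exit offset along the nucleosome axis (nm).
#' @param wrap_offset_nm Center offset into the kink (nm); the offset vector
#'   is `wrap_offset_nm/2 * (t_out - t_in)`, which vanishes smoothly for a
#'   straight pass.
#' @return A list with the new `frame`, and the `entry`, `exit`, `center`
#'   and `axis` of the placed nucleosome.
#' @examples
#' f <- nucleosome_frame()
#' s <- step_geometry(f, alpha = pi, beta = 0, linker_length_nm = 10,
#'                    pitch_d_nm = 0)
#' s$center  # 10 nm straight ahead
#' @export
step_geometry <- function(frame, alpha, beta, linker_length_nm,
                          pitch_d_nm = 0, wrap_offset_nm = 0) {
  validate_frame(frame)
  if (linker_length_nm <= 0) stop("linker_length_nm must be > 0")
  t_in <- frame$t; n <- frame$n
  a <- frame$origin + linker_length_nm * t_in
  th <- pi - alpha
  b <- c(t_in[2] * n[3] - t_in[3] * n[2],
         t_in[3] * n[1] - t_in[1] * n[3],
         t_in[1] * n[2] - t_in[2] * n[1])
  t_out <- .unit(cos(th) * t_in + sin(th) * (cos(beta) * n + sin(beta) * b))
  w <- c(t_in[2] * t_out[3] - t_in[3] * t_out[2],
         t_in[3] * t_out[1] - t_in[1] * t_out[3],
         t_in[1] * t_out[2] - t_in[2] * t_out[1])
  axis <- if (sqrt(sum(w^2)) < 1e-10) n else .unit(w)
  x <- a + pitch_d_nm * axis
  ctr <- (a + x) / 2 + (wrap_offset_nm / 2) * (t_out - t_in)
  nn <- t_in - sum(t_in * t_out) * t_out
  if (sqrt(sum(nn^2)) < 1e-8) nn <- n - sum(n * t_out) * t_out
  newf <- list(origin = x, t = t_out, n = .unit(nn))
  class(newf) <- "nucleosome_frame"
  list(frame = newf, entry = a, exit = x, center = ctr, axis = axis)
}

#' Fit a regular helix through consecutive chain points
#'
#' Closed-form recovery of the helix parameters (axis, radius, rise per
#' step, turn angle per step) from four or more consecutive points of a
#' regular helix, via the constant difference-vector rotation. Used as the
#' independent oracle for constant-angle chains, which must lie on a
#' regular helix.
#'
#' @param pts Matrix (>= 4 rows) of consecutive points.
#' @return List with `axis` (unit vector), `radius` (nm), `rise` (nm/step),
#'   `phi` (radians/step) and `rmse` of the refit.
#' @export
helix_fit <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 4) stop("need at least 4 points")
  d <- diff(pts)
  u <- d[-nrow(d), , drop = FALSE]
  v <- d[-1, , drop = FALSE]
  # axis: difference vectors precess about it; (d1-d2) x (d2-d3) is axial
  ax <- rowSums(vapply(seq_len(nrow(u) - 1), function(i) {
    a <- u[i, ] - v[i, ]; b <- u[i + 1, ] - v[i + 1, ]
    c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
  }, numeric(3)))
  if (sqrt(sum(ax^2)) < 1e-12) {  # straight line
    return(list(axis = .unit(d[1, ]), radius = 0,
                rise = mean(sqrt(rowSums(d^2))), phi = 0, rmse = 0))
  }
  ax <- .unit(ax)
  s <- as.numeric(pts %*% ax)
  k <- seq_len(nrow(pts)) - 1L
  rise <- stats::coef(stats::lm(s ~ k))[["k"]]
  # in-plane coordinates
  e1 <- .unit(d[1, ] - sum(d[1, ] * ax) * ax)
  e2 <- c(ax[2] * e1[3] - ax[3] * e1[2], ax[3] * e1[1] - ax[1] * e1[3],
          ax[1] * e1[2] - ax[2] * e1[1])
  px <- as.numeric(pts %*% e1)
  py <- as.numeric(pts %*% e2)
  # Kasa least-squares circle fit
  A <- cbind(2 * px, 2 * py, 1)
  b <- px^2 + py^2
  sol <- solve(crossprod(A), crossprod(A, b))
  cx <- sol[1]; cy <- sol[2]
  radius <- sqrt(sol[3] + cx^2 + cy^2)
  ang <- atan2(py - cy, px - cx)
  dphi <- diff(ang)
  dphi <- atan2(sin(dphi), cos(dphi))  # wrap to (-pi, pi]
  phi <- abs(mean(dphi))
  rr <- sqrt((px - cx)^2 + (py - cy)^2)
  rmse <- sqrt(mean((rr - radius)^2) +
                 mean((s - (mean(s) + (k - mean(k)) * rise))^2) +
                 stats::var(dphi))
  list(axis = ax, radius = radius, rise = rise, phi = phi, rmse = rmse)
}

#' Excluded-volume clash test between a fiber prefix and a candidate
#'
#' Brute-force (O(N)) clash predicate used as the oracle for the
#' grid-accelerated test inside the growth core. The nucleosome cylinder
#' (11 nm diameter x 5.5 nm height by default) is represented by a fixed
#' 7-sphere decomposition (one central sphere plus six on the mid-plane
#' ring); DNA is a chain of spheres of the DNA excluded-volume radius.
#' Sites closer than one nucleosome repeat along the genome are bonded
#' neighbours and are exempt. Symmetric in pair order.
#'
#' @param fiber_prefix A `"fiber_conformation"` (the already grown part), or
#'   a data frame of excluded-volume spheres as returned by [ev_points()].
#' @param candidate_nucleosome Optional list with `center`, `axis`, `tin`
#'   (numeric length-3 each) and `bp` for a candidate nucleosome.
#' @param candidate_linker Optional matrix of candidate DNA points (rows,
#'   nm) with attribute-free companion vector `candidate_linker_bp`.
#' @param candidate_linker_bp Genomic coordinates (bp) of the linker points.
#' @param params Model parameters; defaults to the prefix fiber's.
#' @return `TRUE` iff any candidate sphere overlaps a non-bonded prefix
#'   sphere.
#' @export
excluded_volume_clash <- function(fiber_prefix, candidate_nucleosome = NULL,
                                  candidate_linker = NULL,
                                  candidate_linker_bp = NULL,
                                  params = NULL) {
  if (inherits(fiber_prefix, "fiber_conformation")) {
    if (is.null(params)) params <- fiber_prefix$params
    prefix <- ev_points(fiber_prefix)
  } else {
    prefix <- fiber_prefix
    if (is.null(params)) params <- e2a_params()
  }
  if (!all(is.finite(as.matrix(prefix[, c("x", "y", "z")]))))
    stop("non-finite geometry in fiber prefix")
  cand <- NULL
  if (!is.null(candidate_nucleosome)) {
    cn <- candidate_nucleosome
    cand <- .nuc_spheres(cn$center, cn$axis, cn$tin, cn$bp, params)
  }
  if (!is.null(candidate_linker)) {
    cl <- as.matrix(candidate_linker)
    bp <- if (is.null(candidate_linker_bp)) rep(NA_real_, nrow(cl)) else
      candidate_linker_bp
    cand <- rbind(cand, data.frame(x = cl[, 1], y = cl[, 2], z = cl[, 3],
                                   r = params$dna_radius_nm, bp = bp))
  }
  if (is.null(cand) || nrow(cand) == 0) return(FALSE)
  for (i in seq_len(nrow(cand))) {
    dx <- prefix$x - cand$x[i]
    dy <- prefix$y - cand$y[i]
    dz <- prefix$z - cand$z[i]
    rr <- prefix$r + cand$r[i]
    bonded <- !is.na(cand$bp[i]) & abs(prefix$bp - cand$bp[i]) < params$nrl_bp
    if (any(!bonded & (dx^2 + dy^2 + dz^2 < rr^2))) return(TRUE)
  }
  FALSE
}

.nuc_spheres <- function(center, axis, tin, bp, params) {
  sub_r <- params$nucleosome_height_nm / 2
  ring_r <- params$nucleosome_radius_nm - sub_r
  u <- c(axis[2] * tin[3] - axis[3] * tin[2],
         axis[3] * tin[1] - axis[1] * tin[3],
         axis[1] * tin[2] - axis[2] * tin[1])
  if (sqrt(sum(u^2)) < 1e-8) u <- c(axis[2], -axis[1], 0)
  if (sqrt(sum(u^2)) < 1e-8) u <- c(0, axis[3], -axis[2])
  u <- .unit(u)
  v <- c(axis[2] * u[3] - axis[3] * u[2], axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  ph <- (0:5) * pi / 3
  ring <- t(vapply(ph, function(a)
    center + ring_r * cos(a) * u + ring_r * sin(a) * v, numeric(3)))
  m <- rbind(center, ring)
  data.frame(x = m[, 1], y = m[, 2], z = m[, 3], r = sub_r, bp = bp)
}

#' Excluded-volume sphere decomposition of a whole fiber
#'
#' Reconstructs, in plain R, the same excluded-volume sphere cloud the
#' growth core uses: 7 spheres per nucleosome, interpolated linker-DNA
#' spheres between consecutive present nucleosomes, and one sphere per
#' naked-DNA vertex. Serves as the independent audit of the simulator's
#' excluded volume.
#'
#' @param fiber A `"fiber_conformation"`.
#' @return Data frame with columns `x, y, z, r, bp`.
#' @export
ev_points <- function(fiber) {
  p <- fiber$params
  out <- list()
  n <- n_nucleosomes(fiber)
  for (i in seq_len(n)) {
    out[[length(out) + 1L]] <-
      .nuc_spheres(fiber$centers[i, ], fiber$axis[i, ], fiber$tin[i, ],
                   fiber$nucleosome_bp[i], p)
  }
  if (n > 1) {
    gi <- fiber$genomic_index
    for (i in seq_len(n - 1)) {
      if (gi[i + 1] != gi[i] + 1L) next  # naked run in between
      from <- fiber$exit[i, ]; to <- fiber$entry[i + 1, ]
      len <- sqrt(sum((to - from)^2))
      m <- max(1L, ceiling(len / (p$dna_seg_bp * p$rise_nm_per_bp)))
      bp_to <- fiber$nucleosome_bp[i + 1] - (p$nrl_bp - p$linker_bp) / 2
      if (m > 1) {
        s <- seq_len(m - 1) / m
        pts <- outer(rep(1, m - 1), from) + outer(s, to - from)
        out[[length(out) + 1L]] <-
          data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                     r = p$dna_radius_nm, bp = bp_to - p$linker_bp +
                       s * p$linker_bp)
      }
    }
  }
  if (nrow(fiber$dna_path) > 0) {
    out[[length(out) + 1L]] <-
      data.frame(x = fiber$dna_path[, 1], y = fiber$dna_path[, 2],
                 z = fiber$dna_path[, 3], r = p$dna_radius_nm,
                 bp = fiber$dna_bp)
  }
  do.call(rbind, out)
}

#' Brute-force excluded-volume audit of a fiber
#'
#' Pairwise O(N^2) overlap scan over the full sphere decomposition,
#' excluding bonded pairs (genomic separation below one repeat length).
#'
#' @param fiber A `"fiber_conformation"`.
#' @return List with `overlap` (logical) and `min_gap` (smallest
#'   surface-to-surface separation over non-bonded pairs, nm).
#' @export
audit_excluded_volume <- function(fiber) {
  ev <- ev_points(fiber)
  n <- nrow(ev)
  if (n < 2) return(list(overlap = FALSE, min_gap = Inf))
  d <- as.matrix(stats::dist(ev[, c("x", "y", "z")]))
  rr <- outer(ev$r, ev$r, "+")
  bonded <- abs(outer(ev$bp, ev$bp, "-")) < fiber$params$nrl_bp
  gap <- d - rr
  gap[bonded] <- Inf
  diag(gap) <- Inf
  mg <- min(gap)
  list(overlap = mg < -1e-9, min_gap = mg)
}
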