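# Random-collision (loop) statistics: contact detection at the interaction
# radius, genomic interaction maps, center-cut profiles, gap widths and
# loop-size distributions.

#' Detect chromatin contacts (loops) in a fiber
#'
#' Two parts of the fiber closer in space than the interaction radius, and
#' farther apart along the genome than `min_separation_bp`, form a contact;
#' the intervening stretch is a loop. Contact sites are either all fiber
#' path points (nucleosome centers plus naked-DNA vertices) or nucleosome
#' centers only. Detection uses a spatial cell grid but is exactly
#' equivalent to the brute-force pair scan.
#'
#' The default genomic exclusion of 15 repeats (about 3 kbp) removes the
#' short-range zigzag order of the fiber interior: separations are excluded
#' while their typical spatial distance, minus five standard deviations of
#' its spread, still reaches the interaction radius (nearest-neighbour
#' distances in the two-angle geometry fall below 35 nm by construction,
#' and the left tail of the zigzag shells clears the radius only beyond
#' about 15 repeats). Only genuine fold-back contacts in the 3C sense are
#' then counted. See the vignette.
#'
#' @param fiber A `"fiber_conformation"`.
#' @param contact_radius_nm Interaction radius (nm).
#' @param min_separation_bp Minimum genomic separation (bp).
#' @param sites `"all"` or `"nucleosomes"`.
#' @return Data frame of class `"loop_records"` with `i_bp`, `j_bp`
#'   (`i_bp < j_bp`), `loop_bp` and `fiber` id.
#' @export
detect_contacts <- function(fiber,
                            contact_radius_nm =
                              fiber$params$contact_radius_nm,
                            min_separation_bp = 15 * fiber$params$nrl_bp,
                            sites = c("all", "nucleosomes")) {
  sites <- match.arg(sites)
  path <- fiber_path(fiber, sites)
  res <- cpp_contacts(path$points, path$bp, contact_radius_nm,
                      min_separation_bp)
  i_bp <- path$bp[res$i]; j_bp <- path$bp[res$j]
  swap <- i_bp > j_bp
  tmp <- i_bp[swap]; i_bp[swap] <- j_bp[swap]; j_bp[swap] <- tmp
  out <- data.frame(i_bp = i_bp, j_bp = j_bp, loop_bp = j_bp - i_bp,
                    fiber = rep(1L, length(i_bp)))
  o <- order(out$i_bp, out$j_bp)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("loop_records", "data.frame")
  out
}

#' Contacts of every fiber in an ensemble
#'
#' @param ensemble A `"fiber_ensemble"`.
#' @param ... Passed to [detect_contacts()].
#' @return A `"loop_records"` data frame with per-fiber ids.
#' @export
ensemble_contacts <- function(ensemble, ...) {
  stopifnot(inherits(ensemble, "fiber_ensemble"))
  recs <- lapply(seq_along(ensemble$fibers), function(i) {
    r <- detect_contacts(ensemble$fibers[[i]], ...)
    if (nrow(r)) r$fiber <- i
    r
  })
  out <- do.call(rbind, recs)
  class(out) <- c("loop_records", "data.frame")
  attr(out, "n_fibers") <- length(ensemble$fibers)
  attr(out, "genomic_length_bp") <- ensemble$config$fiber_length_bp
  out
}

#' Genomic interaction map from contacts
#'
#' Accumulates contact counts into symmetric genomic bins and normalizes by
#' the number of fibers (interaction frequency per fiber) or by the total
#' contact count.
#'
#' @param x A `"fiber_ensemble"`, or `"loop_records"` from
#'   [ensemble_contacts()].
#' @param bin_bp Genomic bin size (bp). The default 2 kbp resolves the
#'   stiffness gap of regular fibers with several bins.
#' @param genomic_length_bp Total genomic extent (needed when `x` is a
#'   contact table without the attribute).
#' @param normalization `"per_fiber"` or `"per_pair"`.
#' @param ... Passed to [ensemble_contacts()] when `x` is an ensemble.
#' @return A `"contact_map"`: list with `matrix` (symmetric), `bin_bp`,
#'   `positions_bp` (bin starts), `n_fibers`, `normalization`,
#'   `min_separation_bp` exclusion note.
#' @export
interaction_map <- function(x, bin_bp = 2000, genomic_length_bp = NULL,
                            normalization = c("per_fiber", "per_pair"),
                            ...) {
  normalization <- match.arg(normalization)
  if (inherits(x, "fiber_ensemble")) {
    recs <- ensemble_contacts(x, ...)
  } else recs <- x
  n_fibers <- attr(recs, "n_fibers")
  if (is.null(n_fibers)) n_fibers <- max(1L, length(unique(recs$fiber)))
  L <- genomic_length_bp
  if (is.null(L)) L <- attr(recs, "genomic_length_bp")
  if (is.null(L)) L <- if (nrow(recs)) max(recs$j_bp) else bin_bp
  nb <- max(1L, ceiling(L / bin_bp))
  m <- matrix(0, nb, nb)
  if (nrow(recs)) {
    bi <- pmin(nb, floor(recs$i_bp / bin_bp) + 1L)
    bj <- pmin(nb, floor(recs$j_bp / bin_bp) + 1L)
    for (k in seq_along(bi)) {
      m[bi[k], bj[k]] <- m[bi[k], bj[k]] + 1
      m[bj[k], bi[k]] <- m[bj[k], bi[k]] + 1
    }
    # the diagonal got double-counted for bi == bj
    d <- bi == bj
    if (any(d)) for (k in which(d)) m[bi[k], bi[k]] <- m[bi[k], bi[k]] - 1
  }
  denom <- switch(normalization, per_fiber = n_fibers,
                  per_pair = max(1, sum(m) / 2))
  out <- list(matrix = m / denom, bin_bp = bin_bp,
              positions_bp = (seq_len(nb) - 1L) * bin_bp,
              n_fibers = n_fibers, normalization = normalization)
  class(out) <- "contact_map"
  out
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("Contact map: %d x %d bins of %.1f kbp (%s normalization, %d fibers)\n",
              nrow(x$matrix), ncol(x$matrix), x$bin_bp / 1000,
              x$normalization, x$n_fibers))
  invisible(x)
}

#' Cut through the interaction map at the fiber center
#'
#' The row of the map through the central genomic bin, re-indexed by signed
#' genomic distance from the center: the interaction frequency of every
#' fiber part with the fiber center. The sign distinguishes the two fiber
#' ends.
#'
#' @param map A `"contact_map"`.
#' @return Data frame of class `"center_cut"` with `distance_bp` (signed)
#'   and `frequency`.
#' @export
center_cut <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  nb <- nrow(map$matrix)
  ctr <- (nb + 1L) %/% 2L
  out <- data.frame(
    distance_bp = (seq_len(nb) - ctr) * map$bin_bp,
    frequency = map$matrix[ctr, ])
  attr(out, "bin_bp") <- map$bin_bp
  class(out) <- c("center_cut", "data.frame")
  out
}

#' Width of the central zero-interaction gap
#'
#' Total genomic width of the region around zero distance where the
#' interaction frequency stays below a threshold fraction of the profile
#' maximum. An all-zero profile returns the full profile width.
#'
#' @param profile A `"center_cut"` data frame.
#' @param threshold_fraction Threshold as a fraction of the maximum.
#' @return Gap width in bp (attribute `kbp` holds the same in kbp).
#' @export
gap_width <- function(profile, threshold_fraction = 0.1) {
  f <- profile$frequency
  d <- profile$distance_bp
  bin <- attr(profile, "bin_bp")
  if (is.null(bin)) bin <- stats::median(diff(sort(d)))
  if (max(f) <= 0) {
    w <- length(f) * bin
  } else {
    thr <- threshold_fraction * max(f)
    below <- f < thr
    ctr <- which.min(abs(d))
    if (!below[ctr]) {
      w <- 0
    } else {
      lo <- ctr
      while (lo > 1 && below[lo - 1]) lo <- lo - 1
      hi <- ctr
      while (hi < length(f) && below[hi + 1]) hi <- hi + 1
      w <- (hi - lo + 1) * bin
    }
  }
  structure(w, kbp = w / 1000)
}

#' Loop-size distribution
#'
#' Normalized histogram of loop lengths (kbp) over a contact table.
#'
#' @param records `"loop_records"` from [detect_contacts()] or
#'   [ensemble_contacts()].
#' @param bin_kbp Bin width in kbp.
#' @return Data frame with `loop_kbp` (bin centers), `density` (1/kbp) and
#'   `count`; attribute `min_loop_kbp` reports the smallest observed loop.
#'   Empty input gives zero rows.
#' @export
loop_size_distribution <- function(records, bin_kbp = 1) {
  if (nrow(records) == 0) {
    out <- data.frame(loop_kbp = numeric(), density = numeric(),
                      count = numeric())
    attr(out, "min_loop_kbp") <- NA_real_
    return(out)
  }
  kbp <- records$loop_bp / 1000
  nb <- ceiling(max(kbp) / bin_kbp)
  b <- pmin(nb, floor(kbp / bin_kbp) + 1L)
  cnt <- tabulate(b, nbins = nb)
  out <- data.frame(loop_kbp = (seq_len(nb) - 0.5) * bin_kbp,
                    density = cnt / (sum(cnt) * bin_kbp), count = cnt)
  attr(out, "min_loop_kbp") <- min(kbp)
  out
}

#' Read a tab-separated interaction-frequency matrix
#'
#' Parses a position x position matrix in the layout written by
#' [write_interaction_table()]: optional `#key=value` metadata lines, a
#' header row of bin start coordinates (bp), and one row per bin starting
#' with its coordinate. Asymmetric input is symmetrized to the mean of
#' (i,j) and (j,i) with a warning.
#'
#' @param path File path.
#' @return A `"contact_map"`.
#' @export
read_interaction_table <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines)
  body <- if (length(meta)) lines[-meta] else lines
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2)
    stop("interaction table needs a header row and at least one data row")
  split_row <- function(s) strsplit(s, "\t", fixed = TRUE)[[1]]
  hdr <- split_row(body[1])
  if (length(hdr) < 2 || nzchar(trimws(hdr[1])))
    stop("line 1: missing coordinate header (first field must be empty)")
  pos <- suppressWarnings(as.numeric(hdr[-1]))
  if (anyNA(pos)) stop("line 1: non-numeric bin coordinate in header")
  nb <- length(pos)
  m <- matrix(NA_real_, nb, nb)
  if (length(body) - 1 != nb)
    stop(sprintf("expected %d data rows, found %d", nb, length(body) - 1))
  for (k in seq_len(nb)) {
    f <- split_row(body[k + 1])
    if (length(f) != nb + 1)
      stop(sprintf("line %d: expected %d fields, found %d", k + 1, nb + 1,
                   length(f)))
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) stop(sprintf("line %d: non-numeric entry", k + 1))
    m[k, ] <- v
  }
  if (max(abs(m - t(m))) > 1e-12 * max(1, max(abs(m)))) {
    warning("asymmetric interaction table symmetrized to the mean of (i,j) and (j,i)")
    m <- (m + t(m)) / 2
  }
  bin <- if (nb > 1) stats::median(diff(pos)) else pos[1] + 1
  out <- list(matrix = m, bin_bp = bin, positions_bp = pos,
              n_fibers = NA_integer_, normalization = "as_read")
  class(out) <- "contact_map"
  out
}

#' Write a contact map as a tab-separated matrix
#'
#' @param map A `"contact_map"`.
#' @param path Output path.
#' @param meta Named character vector of extra `#key=value` header lines.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(map, path, meta = NULL) {
  stopifnot(inherits(map, "contact_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#bin_bp=%s", format(map$bin_bp)), con)
  if (!is.null(meta))
    writeLines(sprintf("#%s=%s", names(meta), meta), con)
  fmt <- function(v) sub("\\.?0+$", "", sprintf("%.10f", v))
  writeLines(paste(c("", format(map$positions_bp, scientific = FALSE,
                                trim = TRUE)), collapse = "\t"), con)
  for (k in seq_len(nrow(map$matrix)))
    writeLines(paste(c(format(map$positions_bp[k], scientific = FALSE,
                              trim = TRUE), fmt(map$matrix[k, ])),
                     collapse = "\t"), con)
  invisible(path)
}
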