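# Fiber stiffness estimation and calibration of the default angle
# distributions.

#' Smoothed fiber-axis path
#'
#' Local fiber-axis estimate: moving average of the nucleosome centers over
#' a window (default 5 nucleosomes). The persistence length of the 30 nm
#' fiber describes this axis, not the zigzagging nucleosome chain or the
#' linker DNA.
#'
#' @param fiber A `"fiber_conformation"` or a point matrix (path vertices).
#' @param window Moving-average window (sites); 1 returns the raw path.
#' @return Matrix of axis points (nm).
#' @export
fiber_axis <- function(fiber, window = 5) {
  pts <- if (inherits(fiber, "fiber_conformation")) {
    if (n_nucleosomes(fiber) > 0) fiber$centers else fiber$dna_path
  } else as.matrix(fiber)
  n <- nrow(pts)
  if (window <= 1 || n <= window) return(pts)
  cs <- apply(pts, 2, cumsum)
  idx <- seq_len(n - window + 1)
  (cs[idx + window - 1, , drop = FALSE] -
      rbind(0, cs)[idx, , drop = FALSE]) / window
}

.tangent_corr <- function(axis_pts, max_lag) {
  d <- diff(axis_pts)
  len <- sqrt(rowSums(d^2))
  t <- d / len
  nl <- min(max_lag, nrow(t) - 1)
  corr <- vapply(seq_len(nl), function(k) {
    i <- seq_len(nrow(t) - k)
    mean(rowSums(t[i, , drop = FALSE] * t[i + k, , drop = FALSE]))
  }, numeric(1))
  list(lag = seq_len(nl), corr = corr, step = mean(len),
       contour = sum(len))
}

#' Persistence length and linear compaction of a fiber ensemble
#'
#' Default estimator: exponential fit to the tangent--tangent correlation
#' \eqn{\langle t(s) \cdot t(s + \Delta s)\rangle = e^{-\Delta s / L_p}}
#' along the smoothed fiber axis, by weighted least squares on the log
#' correlations averaged over fibers. The alternative `"end_to_end"`
#' estimator inverts the worm-like-chain relation
#' \eqn{\langle R^2 \rangle = 2 L_p L (1 - \frac{L_p}{L}(1 -
#' e^{-L/L_p}))}. Confidence intervals come from a bootstrap over fibers.
#' Linear compaction is genomic length per fiber-axis contour length, and
#' the genomic persistence length is their product.
#'
#' @param x A `"fiber_ensemble"`, `"fiber_conformation"`, point matrix or
#'   list of point matrices.
#' @param window Fiber-axis smoothing window (sites); use 1 for plain
#'   polymer paths such as naked DNA.
#' @param method `"tangent"` (default) or `"end_to_end"`.
#' @param fit_floor Smallest correlation used in the log-linear fit.
#' @param n_boot Bootstrap replicates for the CI (0 disables).
#' @param genomic_length_bp Override for plain point inputs.
#' @return A `"stiffness_report"`: list with `lp_nm`, `lp_ci_nm`,
#'   `compaction_bp_per_nm`, `compaction_ci`, `genomic_lp_kbp`, `method`,
#'   `fit` diagnostics.
#' @export
persistence_length <- function(x, window = 5,
                               method = c("tangent", "end_to_end"),
                               fit_floor = 0.15, n_boot = 50,
                               genomic_length_bp = NULL) {
  method <- match.arg(method)
  paths <- if (inherits(x, "fiber_ensemble")) {
    lapply(x$fibers, fiber_axis, window = window)
  } else if (inherits(x, "fiber_conformation")) {
    list(fiber_axis(x, window))
  } else if (is.matrix(x)) list(fiber_axis(x, window))
  else lapply(x, fiber_axis, window = window)
  if (is.null(genomic_length_bp)) {
    genomic_length_bp <- if (inherits(x, "fiber_ensemble"))
      x$config$fiber_length_bp
    else if (inherits(x, "fiber_conformation")) x$genomic_length_bp
    else NA_real_
  }

  est <- function(idx) {
    ps <- paths[idx]
    if (method == "tangent") {
      ccs <- lapply(ps, .tangent_corr, max_lag = max(10, window * 40))
      nl <- min(vapply(ccs, function(c) length(c$lag), integer(1)))
      corr <- rowMeans(vapply(ccs, function(c) c$corr[seq_len(nl)],
                              numeric(nl)))
      step <- mean(vapply(ccs, function(c) c$step, numeric(1)))
      # skip lags inside the smoothing window; stop where correlations are
      # too noisy for the log fit
      lo <- min(window, nl)
      hi <- which(corr < fit_floor)[1]
      hi <- if (is.na(hi)) nl else max(hi - 1, lo + 1)
      use <- lo:hi
      use <- use[corr[use] > 0]
      if (length(use) < 2)
        stop("tangent correlation does not decay over the available range; ",
             "fiber too short or rod-like for the tangent estimator")
      s <- use * step
      fit <- stats::lm(log(corr[use]) ~ s, weights = corr[use]^2)
      slope <- stats::coef(fit)[["s"]]
      if (slope >= 0)
        stop("non-decaying tangent correlation: cannot estimate Lp")
      lp <- -1 / slope
      list(lp = lp, fit = list(lag_nm = s, corr = corr[use],
                               r2 = summary(fit)$r.squared))
    } else {
      r2e <- vapply(ps, function(p) sum((p[nrow(p), ] - p[1, ])^2),
                    numeric(1))
      L <- mean(vapply(ps, function(p) sum(sqrt(rowSums(diff(p)^2))),
                       numeric(1)))
      target <- mean(r2e)
      wlc <- function(lp) 2 * lp * L * (1 - lp / L * (1 - exp(-L / lp)))
      if (target >= L^2 * 0.999)
        stop("chain is rod-like: end-to-end estimator cannot resolve Lp")
      lp <- stats::uniroot(function(lp) wlc(lp) - target,
                           interval = c(1e-3, 1e3 * L))$root
      list(lp = lp, fit = list(mean_r2 = target, contour = L))
    }
  }

  full <- est(seq_along(paths))
  contour <- mean(vapply(paths, function(p) sum(sqrt(rowSums(diff(p)^2))),
                         numeric(1)))
  comp <- if (is.na(genomic_length_bp)) NA_real_ else
    genomic_length_bp / contour
  lp_ci <- c(NA_real_, NA_real_)
  comp_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0 && length(paths) > 1) {
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample(seq_along(paths), replace = TRUE)
      lpb <- tryCatch(est(idx)$lp, error = function(e) NA_real_)
      cb <- if (is.na(genomic_length_bp)) NA_real_ else genomic_length_bp /
        mean(vapply(paths[idx],
                    function(p) sum(sqrt(rowSums(diff(p)^2))), numeric(1)))
      c(lpb, cb)
    }, numeric(2))
    lp_ci <- stats::quantile(boots[1, ], c(0.025, 0.975), na.rm = TRUE)
    comp_ci <- stats::quantile(boots[2, ], c(0.025, 0.975), na.rm = TRUE)
  }
  out <- list(lp_nm = full$lp, lp_ci_nm = as.numeric(lp_ci),
              compaction_bp_per_nm = comp,
              compaction_ci = as.numeric(comp_ci),
              genomic_lp_kbp = if (is.na(comp)) NA_real_ else
                full$lp * comp / 1000,
              method = method, window = window, n_fibers = length(paths),
              fit = full$fit)
  class(out) <- "stiffness_report"
  out
}

#' @export
print.stiffness_report <- function(x, ...) {
  cat(sprintf("Persistence length: %.1f nm (95%% CI %.1f-%.1f), %s estimator\n",
              x$lp_nm, x$lp_ci_nm[1], x$lp_ci_nm[2], x$method))
  if (!is.na(x$compaction_bp_per_nm))
    cat(sprintf("  compaction %.2f bp/nm -> genomic Lp %.2f kbp\n",
                x$compaction_bp_per_nm, x$genomic_lp_kbp))
  invisible(x)
}

#' Calibrate the default angle-distribution constants
#'
#' Two-stage derivative-free search for the model constants that are not
#' fixed by the repeat geometry: the effective linker length and the means
#' of \eqn{\alpha} and \eqn{\beta} are first fitted to the target mean
#' distances at genomic separations 1, 2 and 10 on the noise-free chain;
#' then the angle SDs and the linker-length spread are fitted to the
#' nearest-neighbour mean and spread, the spreads at separations 2 and 10,
#' and the regular-fiber persistence length, with the mean geometry
#' re-polished under noise. Optionally, the width of the released opening-angle
#' interval for linker-histone skips is calibrated against a disturbed-
#' fiber persistence-length target. Deterministic given `seed` (common
#' random numbers per objective evaluation).
#'
#' @param targets Named list of anchors: `r1_mean`, `r1_sd`, `r2_mean`,
#'   `r2_sd`, `r10_mean` (nm), `lp_regular` (nm), optional `lp_disturbed`
#'   (nm). `NULL` entries are ignored.
#' @param base An `"e2a_params"` providing everything not calibrated.
#' @param n_fibers,fiber_nucleosomes Ensemble size per stochastic
#'   objective evaluation.
#' @param maxit Nelder-Mead iteration budget per stage.
#' @param seed RNG seed for the objective evaluations.
#' @param tol_frac Maximum acceptable relative residual per target;
#'   exceeding it raises a calibration-failure error with the residuals.
#' @return List of class `"e2a_calibration"` with `params` (calibrated
#'   `"e2a_params"`), `residuals` (named relative errors), `achieved`
#'   (measured values) and `constants` (the frozen numbers).
#' @export
calibrate_defaults <- function(targets = list(r1_mean = 51.00, r1_sd = 0.63,
                                              r2_mean = 37.55, r2_sd = 7.16,
                                              r10_mean = 125.06,
                                              lp_regular = 280,
                                              lp_disturbed = NULL),
                               base = e2a_params(),
                               n_fibers = 12, fiber_nucleosomes = 600,
                               maxit = 150, seed = 421, tol_frac = 0.10) {
  tg <- targets[!vapply(targets, is.null, logical(1))]
  if (is.null(tg$r1_mean)) stop("target r1_mean is required")
  if (tg$r1_mean < 2 * base$nucleosome_radius_nm)
    stop(sprintf(paste0("calibration-failure: target r1_mean %.1f nm is below",
                        " the nucleosome diameter %.1f nm"),
                 tg$r1_mean, 2 * base$nucleosome_radius_nm))

  det_rdelta <- function(l, a0, b0) {
    # noise-free chain -> exact r_Delta
    p <- .with_angles(base, l, a0, 0, b0, 0, 0)
    cfg <- sim_config(p, fiber_length_bp = 20 * p$nrl_bp, seed = 1,
                      growth_max_retries = 0)
    f <- grow_fiber(cfg, mask = defect_mask(rep("regular", 20), p))
    ctr <- f$centers
    mid <- 8
    vapply(c(1, 2, 10), function(d)
      sqrt(sum((ctr[mid + d, ] - ctr[mid, ])^2)), numeric(1))
  }

  stage1_obj <- function(x) {
    l <- exp(x[1]); a0 <- pi / (1 + exp(-x[2])); b0 <- x[3]
    r <- tryCatch(det_rdelta(l, a0, b0), error = function(e) c(NA, NA, NA))
    if (anyNA(r)) return(1e6)
    e <- (r[1] - tg$r1_mean)^2 / tg$r1_mean^2
    if (!is.null(tg$r2_mean)) e <- e + (r[2] - tg$r2_mean)^2 / tg$r2_mean^2
    if (!is.null(tg$r10_mean))
      e <- e + (r[3] - tg$r10_mean)^2 / tg$r10_mean^2
    e
  }
  starts <- expand.grid(a = c(0.4, 0.7, 1.0, 1.4), b = c(-2.5, -1.5, 1.5,
                                                         2.5))
  s1 <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(c(log(tg$r1_mean * 1.1),
                        stats::qlogis(starts$a[i] / pi), starts$b[i]),
                      stage1_obj, method = "Nelder-Mead",
                      control = list(maxit = maxit * 4, reltol = 1e-12))
    if (is.null(s1) || o$value < s1$value) s1 <- o
  }
  l1 <- exp(s1$par[1]); a1 <- pi / (1 + exp(-s1$par[2])); b1 <- s1$par[3]

  measure <- function(p, lp_needed = TRUE, disturbed = FALSE) {
    pp <- p
    if (!disturbed) {
      pp$p_nuc_skip <- 0; pp$p_lh_skip <- 0
    }
    set.seed(seed)
    cfg <- sim_config(pp, fiber_length_bp = fiber_nucleosomes * pp$nrl_bp,
                      n_fibers = n_fibers, seed = seed)
    ens <- simulate_ensemble(cfg)
    rd <- r_delta_stats(ens, delta_max = 10)
    lp <- if (lp_needed)
      tryCatch(persistence_length(ens, n_boot = 0)$lp_nm,
               error = function(e) NA_real_) else NA_real_
    list(r1 = rd$mean[1], r1_sd = rd$sd[1], r2 = rd$mean[2],
         r2_sd = rd$sd[2], r10 = rd$mean[10], lp = lp)
  }

  need_lp <- !is.null(tg$lp_regular)
  stage2_obj <- function(x) {
    sa <- exp(x[1]); sb <- exp(x[2]); ls <- exp(x[3])
    l <- exp(x[4]); a0 <- pi / (1 + exp(-x[5])); b0 <- x[6]
    p <- .with_angles(base, l, a0, sa, b0, sb, ls)
    m <- tryCatch(measure(p, lp_needed = need_lp),
                  error = function(e) NULL)
    if (is.null(m) || anyNA(unlist(m[c("r1", "r1_sd")]))) return(1e6)
    e <- (m$r1 - tg$r1_mean)^2 / tg$r1_mean^2
    if (!is.null(tg$r1_sd)) e <- e + (m$r1_sd - tg$r1_sd)^2 / tg$r1_sd^2
    if (!is.null(tg$r2_mean)) e <- e + (m$r2 - tg$r2_mean)^2 / tg$r2_mean^2
    if (!is.null(tg$r2_sd)) e <- e + (m$r2_sd - tg$r2_sd)^2 / tg$r2_sd^2
    if (!is.null(tg$r10_mean)) e <- e + (m$r10 - tg$r10_mean)^2 /
        tg$r10_mean^2
    if (need_lp) {
      if (is.na(m$lp)) return(1e6)
      e <- e + (m$lp - tg$lp_regular)^2 / tg$lp_regular^2
    }
    e
  }
  start2 <- c(log(0.12), log(0.3), log(0.6), log(l1),
              stats::qlogis(a1 / pi), b1)
  s2 <- stats::optim(start2, stage2_obj, method = "Nelder-Mead",
                     control = list(maxit = maxit * 2, reltol = 1e-6))
  sa <- exp(s2$par[1]); sb <- exp(s2$par[2]); ls <- exp(s2$par[3])
  l2 <- exp(s2$par[4]); a2 <- pi / (1 + exp(-s2$par[5])); b2 <- s2$par[6]
  params <- .with_angles(base, l2, a2, sa, b2, sb, ls)

  # stage 3: released opening-angle interval width against the disturbed
  # persistence length (optional)
  if (!is.null(tg$lp_disturbed)) {
    obj3 <- function(w) {
      p <- params
      p$lh_alpha_range <- c(max(1e-3, a2 - w), min(pi - 1e-3, a2 + w))
      m <- tryCatch(measure(p, disturbed = TRUE),
                    error = function(e) NULL)
      if (is.null(m) || is.na(m$lp)) return(1e6)
      (m$lp - tg$lp_disturbed)^2 / tg$lp_disturbed^2
    }
    # the released interval must be at least as broad as the constrained
    # Gaussian (half-width 2.5 SD), otherwise losing the linker histone
    # would stiffen the fiber
    w_min <- 2.5 * sa
    ws <- seq(w_min, 2.6, length.out = 7)
    vals <- vapply(ws, obj3, numeric(1))
    w <- ws[which.min(vals)]
    o <- stats::optimize(obj3, interval = c(max(w_min, w - 0.4),
                                            min(ws[length(ws)], w + 0.4)))
    w <- o$minimum
    params$lh_alpha_range <- c(max(1e-3, a2 - w), min(pi - 1e-3, a2 + w))
  }

  ach <- measure(params, lp_needed = need_lp)
  res <- c(r1_mean = (ach$r1 - tg$r1_mean) / tg$r1_mean)
  if (!is.null(tg$r1_sd))
    res["r1_sd"] <- (ach$r1_sd - tg$r1_sd) / tg$r1_sd
  if (!is.null(tg$r2_mean))
    res["r2_mean"] <- (ach$r2 - tg$r2_mean) / tg$r2_mean
  if (!is.null(tg$r2_sd))
    res["r2_sd"] <- (ach$r2_sd - tg$r2_sd) / tg$r2_sd
  if (!is.null(tg$r10_mean))
    res["r10_mean"] <- (ach$r10 - tg$r10_mean) / tg$r10_mean
  if (need_lp) res["lp_regular"] <- (ach$lp - tg$lp_regular) / tg$lp_regular
  if (!is.null(tg$lp_disturbed)) {
    md <- measure(params, disturbed = TRUE)
    res["lp_disturbed"] <- (md$lp - tg$lp_disturbed) / tg$lp_disturbed
    ach$lp_disturbed <- md$lp
  }
  if (any(abs(res) > tol_frac))
    stop(sprintf("calibration-failure: residuals exceed %.0f%%: %s",
                 100 * tol_frac,
                 paste(sprintf("%s=%+.1f%%", names(res), 100 * res),
                       collapse = ", ")))
  out <- list(params = params, residuals = res, achieved = ach,
              constants = list(linker_length_nm = params$linker_length_nm,
                               linker_length_sd_nm =
                                 params$linker_length_sd_nm,
                               alpha_mean = params$alpha_mean,
                               alpha_sd = params$alpha_sd,
                               beta_mean = params$beta_mean,
                               beta_sd = params$beta_sd,
                               lh_alpha_range = params$lh_alpha_range))
  class(out) <- "e2a_calibration"
  out
}

.with_angles <- function(base, l, a0, sa, b0, sb, ls = NULL) {
  p <- base
  p$linker_length_nm <- l
  p$alpha_mean <- a0
  p$alpha_sd <- sa
  p$beta_mean <- b0
  p$beta_sd <- sb
  if (!is.null(ls)) p$linker_length_sd_nm <- ls
  validate_e2a_params(p)
  p
}

#' @export
print.e2a_calibration <- function(x, ...) {
  cat("Calibrated E2A defaults:\n")
  for (nm in names(x$constants))
    cat(sprintf("  %s = %s\n", nm,
                paste(signif(x$constants[[nm]], 6), collapse = ", ")))
  cat("Residuals: ",
      paste(sprintf("%s %+.1f%%", names(x$residuals), 100 * x$residuals),
            collapse = ", "), "\n")
  invisible(x)
}
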