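# Two-tissue partial-volume model for quantitative T1 maps.
#
# Model: y_i = mu_gm * c_i + mu_wm * (1 - c_i) + eps_i, eps_i ~ N(0, sigma),
# with c_i in [0, 1] the local GM concentration and (mu_gm, mu_wm) global to
# the region. The fit alternates between re-estimating the concentration map
# given the characteristic intensities and re-estimating the intensities
# given the concentrations.
#
# The least-squares objective alone is degenerate: any intensity pair whose
# interval covers the data range reproduces the data exactly with interior
# concentrations, so the likelihood must account for where concentrations
# come from. The intensity update therefore maximizes the marginal
# likelihood under a uniform concentration prior,
#   p(y | mu_gm, mu_wm, sigma)
#     = [Phi((y - mu_wm)/sigma) - Phi((y - mu_gm)/sigma)] / (mu_gm - mu_wm),
# with the intensities constrained to the observed intensity range. In the
# noise-free limit this selects the tightest interval covering the data,
# which equals the true pair whenever the region contains (nearly) pure
# voxels of both tissues, and with noise it is a consistent ML estimator.

#' Characteristic tissue intensities
#'
#' The pair of T1 values corresponding to 100% gray and 100% white matter
#' inside one region, plus the residual noise SD.
#'
#' @param mu_gm Characteristic GM T1 (ms); must exceed `mu_wm`.
#' @param mu_wm Characteristic WM T1 (ms); must be positive.
#' @param sigma Residual noise SD (ms), `NA` if not estimated.
#' @return An object of class `tissue_intensities`.
#' @export
tissue_intensities <- function(mu_gm, mu_wm, sigma = NA_real_) {
  if (!is.finite(mu_gm) || !is.finite(mu_wm) || mu_wm <= 0)
    stop("characteristic intensities must be finite and positive", call. = FALSE)
  if (mu_gm <= mu_wm)
    stop("non-identifiable intensities: mu_gm must exceed mu_wm (got ",
         round(mu_gm, 3), " <= ", round(mu_wm, 3), ")", call. = FALSE)
  if (!is.na(sigma) && sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(mu_gm = mu_gm, mu_wm = mu_wm, sigma = sigma),
            class = "tissue_intensities")
}

#' @export
print.tissue_intensities <- function(x, ...) {
  cat(sprintf("<tissue_intensities> mu_gm = %.1f ms, mu_wm = %.1f ms, sigma = %s ms\n",
              x$mu_gm, x$mu_wm,
              if (is.na(x$sigma)) "NA" else sprintf("%.1f", x$sigma)))
  invisible(x)
}

#' Per-voxel GM concentration field
#'
#' Stores only the GM fraction; the WM fraction is `1 - c_gm` under the
#' two-tissue closure and is never stored independently.
#'
#' @param c_gm Numeric vector of GM fractions in `[0, 1]`.
#' @param voxels Optional integer vector of linear voxel indices into the
#'   source grid (used to write maps back into volumes).
#' @return An object of class `concentration_field`.
#' @export
concentration_field <- function(c_gm, voxels = NULL) {
  if (!is.numeric(c_gm) || length(c_gm) == 0)
    stop("empty concentration field", call. = FALSE)
  if (any(c_gm < -1e-12 | c_gm > 1 + 1e-12, na.rm = TRUE))
    stop("concentrations must lie in [0, 1]", call. = FALSE)
  c_gm <- pmin(1, pmax(0, c_gm))
  if (!is.null(voxels) && length(voxels) != length(c_gm))
    stop("'voxels' must match the field length", call. = FALSE)
  structure(list(c_gm = c_gm, voxels = voxels), class = "concentration_field")
}

as_cgm <- function(c) {
  if (inherits(c, "concentration_field")) c$c_gm else as.numeric(c)
}

#' Step 1: estimate the concentration map given tissue intensities
#'
#' Per voxel, the least-squares GM fraction under the sum-to-one constraint,
#' clamped to `[0, 1]`:
#' `c_gm = clamp((y - mu_wm) / (mu_gm - mu_wm), 0, 1)`.
#' Voxels brighter than `mu_gm` or darker than `mu_wm` saturate at the
#' bounds.
#'
#' @param y Numeric vector of voxel T1 values (ms).
#' @param intensities A [tissue_intensities] with `mu_gm > mu_wm`.
#' @return A [concentration_field].
#' @export
estimate_concentrations <- function(y, intensities) {
  stopifnot(inherits(intensities, "tissue_intensities"))
  raw <- (y - intensities$mu_wm) / (intensities$mu_gm - intensities$mu_wm)
  concentration_field(pmin(1, pmax(0, raw)))
}

#' Step 2 (fixed concentrations): least-squares tissue intensities
#'
#' Ordinary least squares of `y` on the regressors `(c, 1 - c)` solved in
#' closed form from the 2x2 normal equations;
#' `sigma = sqrt(RSS / N)` is the maximum-likelihood residual SD.
#'
#' This is the classical fixed-concentration update. [fit_pve] augments it
#' with a concentration-uncertainty (marginal likelihood) refinement, which
#' is what makes the alternation identifiable; see the package vignette.
#'
#' @param y Numeric vector of voxel T1 values (ms).
#' @param c A [concentration_field] or numeric vector of GM fractions with
#'   at least two distinct values.
#' @return A [tissue_intensities] with estimated `sigma`.
#' @export
estimate_tissue_intensities <- function(y, c) {
  cc <- as_cgm(c)
  if (length(y) != length(cc)) stop("y and c lengths differ", call. = FALSE)
  s11 <- sum(cc * cc); s12 <- sum(cc * (1 - cc)); s22 <- sum((1 - cc)^2)
  det <- s11 * s22 - s12 * s12
  if (det <= 1e-10 * max(s11 + s22, 1))
    stop("degenerate fit: concentrations are (nearly) constant, ",
         "tissue intensities are not identifiable for this ROI", call. = FALSE)
  t1 <- sum(cc * y); t2 <- sum((1 - cc) * y)
  mu_gm <- (s22 * t1 - s12 * t2) / det
  mu_wm <- (s11 * t2 - s12 * t1) / det
  rss <- sum((y - mu_gm * cc - mu_wm * (1 - cc))^2)
  tissue_intensities(mu_gm, mu_wm, sigma = sqrt(max(rss, 0) / length(y)))
}

#' Residual sum of squares of the mixture model
#'
#' `sum((y - mu_gm * c - mu_wm * (1 - c))^2)`. Invariant under the label
#' swap `(mu_gm, mu_wm, c) -> (mu_wm, mu_gm, 1 - c)`; the ordering rule
#' `mu_gm > mu_wm` picks one representative of each such pair.
#'
#' @param y Numeric vector of voxel T1 values (ms).
#' @param c A [concentration_field] or numeric vector of GM fractions.
#' @param intensities A [tissue_intensities] (ordering is not required
#'   here, so a bare `list(mu_gm =, mu_wm =)` is also accepted).
#' @return RSS in ms^2.
#' @export
pve_objective <- function(y, c, intensities) {
  cc <- as_cgm(c)
  sum((y - intensities$mu_gm * cc - intensities$mu_wm * (1 - cc))^2)
}

# Negative log marginal likelihood of (u, v, log sigma), where
# mu_wm = lo + u, mu_gm = hi - v; lo/hi are the observed data range.
pve_nll <- function(par, y, lo, hi) {
  u <- par[1]; v <- par[2]; s <- exp(par[3])
  b <- lo + u; a <- hi - v
  delta <- a - b
  if (!is.finite(delta) || delta <= 1e-8) return(1e12)
  z1 <- (y - b) / s; z2 <- (y - a) / s
  # Phi(z1) - Phi(z2) with z1 > z2, evaluated in whichever tail is stable
  lp <- numeric(length(y))
  up <- z1 + z2 > 0
  if (any(up))
    lp[up] <- log(stats::pnorm(z2[up], lower.tail = FALSE) -
                    stats::pnorm(z1[up], lower.tail = FALSE))
  if (!all(up))
    lp[!up] <- log(stats::pnorm(z1[!up]) - stats::pnorm(z2[!up]))
  bad <- !is.finite(lp)
  if (any(bad)) {
    l1 <- stats::pnorm(z1, log.p = TRUE)
    l2 <- stats::pnorm(z2, log.p = TRUE)
    lp[bad] <- (l1 + log1p(-pmin(exp(l2 - l1), 1 - 1e-16)))[bad]
    if (any(!is.finite(lp))) return(1e12)
  }
  -sum(lp) + length(y) * log(delta)
}

# analytic gradient of pve_nll in (u, v, log sigma)
pve_nll_grad <- function(par, y, lo, hi) {
  u <- par[1]; v <- par[2]; s <- exp(par[3])
  b <- lo + u; a <- hi - v
  delta <- a - b
  if (!is.finite(delta) || delta <= 1e-8) return(c(0, 0, 0))
  z1 <- (y - b) / s; z2 <- (y - a) / s
  up <- z1 + z2 > 0
  P <- numeric(length(y))
  P[up] <- stats::pnorm(z2[up], lower.tail = FALSE) -
    stats::pnorm(z1[up], lower.tail = FALSE)
  P[!up] <- stats::pnorm(z1[!up]) - stats::pnorm(z2[!up])
  P <- pmax(P, 1e-300)
  f1 <- stats::dnorm(z1); f2 <- stats::dnorm(z2)
  n <- length(y)
  du <- sum(f1 / P) / s - n / delta
  dv <- sum(f2 / P) / s - n / delta
  dls <- -sum((z2 * f2 - z1 * f1) / P)
  g <- c(du, dv, dls)
  g[!is.finite(g)] <- 0
  g
}

refit_intensities_ml <- function(y, par, lo, hi, sigma_floor = 1e-4,
                                 extra_starts = list()) {
  ctrl <- list(rel.tol = 1e-9, x.tol = 1e-9, iter.max = 300, eval.max = 500)
  ls_lo <- log(sigma_floor); ls_hi <- log(max(hi - lo, 1))
  best <- NULL; best_val <- Inf
  for (start in c(list(par), extra_starts)) {
    opt <- stats::nlminb(start, .pve_nll_cpp, gradient = .pve_nll_grad_cpp,
                         y = y, lo = lo, hi = hi,
                         lower = c(0, 0, ls_lo),
                         upper = c(hi - lo, hi - lo, ls_hi),
                         control = ctrl)
    if (opt$objective < best_val) { best <- opt$par; best_val <- opt$objective }
  }
  # polish: the noise-free optimum sits on the range constraints, where
  # box-constrained quasi-Newton steps can stall short; when the solution
  # is near a constraint, re-test the constraint-active candidates with
  # sigma re-optimized in 1D
  fitted_width <- (hi - lo) - best[1] - best[2]
  if (min(best[1], best[2]) < 5 || fitted_width < 0.5 * (hi - lo)) {
    for (cand in list(c(0, best[2]), c(best[1], 0), c(0, 0))) {
      o1 <- stats::optimize(function(ls) .pve_nll_cpp(c(cand, ls), y, lo, hi),
                            c(ls_lo, ls_hi), tol = 1e-8)
      if (o1$objective < best_val - 1e-10) {
        best <- c(cand, o1$minimum); best_val <- o1$objective
      }
    }
  }
  list(par = best, objective = best_val)
}

#' Fit the partial-volume model to a vector of voxel intensities
#'
#' Alternates (Step 1) the clamped concentration update
#' [estimate_concentrations] and (Step 2) re-estimation of
#' `(mu_gm, mu_wm, sigma)` by marginal maximum likelihood under a uniform
#' concentration prior, with the intensities constrained to the observed
#' intensity range (`min(y) <= mu_wm < mu_gm <= max(y)`). The default of
#' 10 iterations gives stable estimates; the inner intensity update is
#' solved to convergence, so the outer alternation typically reaches its
#' fixed point after one or two iterations and later iterations leave the
#' estimates unchanged.
#'
#' @param y Numeric vector of at least 3 voxel T1 values (ms).
#' @param init A [tissue_intensities] used to start the alternation;
#'   defaults to standard 3T values, 1350 ms (GM) and 850 ms (WM).
#' @param n_iter Number of alternation iterations (default 10).
#' @param tol Early-stop tolerance (ms) on the maximum change of the
#'   characteristic intensities; 0 (default) disables early stopping.
#' @return An object of class `pve_fit` with elements `intensities`
#'   (a [tissue_intensities]; `sigma` is the maximum-likelihood noise SD,
#'   essentially 0 for noise-free data), `concentrations`
#'   (a [concentration_field]), `rss_trace` (RSS of the clamped
#'   concentration fit in ms^2 after each iteration, non-increasing),
#'   `sigma_rss` (`sqrt(RSS/N)` of the final clamped fit; an
#'   underestimate of the noise because interior voxels are fitted
#'   exactly), `n_iterations`, `converged_early` and `n_voxels`.
#' @export
fit_pve <- function(y, init = tissue_intensities(1350, 850), n_iter = 10,
                    tol = 0) {
  y <- as.numeric(y)
  if (length(y) < 3) stop("need at least 3 voxels", call. = FALSE)
  if (any(!is.finite(y))) stop("y must be finite", call. = FALSE)
  stopifnot(inherits(init, "tissue_intensities"), n_iter >= 1, tol >= 0)
  lo <- min(y); hi <- max(y)
  if (hi - lo <= 1e-8 * max(abs(hi), 1))
    stop("non-identifiable ROI: all voxels map to a single concentration ",
         "(constant intensities)", call. = FALSE)

  # start from the initialization, projected into the feasible box; fall
  # back to the full data range when the projection is (nearly) degenerate
  u <- max(init$mu_wm - lo, 0)
  v <- max(hi - init$mu_gm, 0)
  if ((hi - v) - (lo + u) < 0.5 * (hi - lo)) { u <- 0; v <- 0 }
  c0 <- pmin(1, pmax(0, (y - init$mu_wm) / (init$mu_gm - init$mu_wm)))
  s0 <- sqrt(max(mean((y - init$mu_wm - (init$mu_gm - init$mu_wm) * c0)^2),
                 1e-4))
  par <- c(u, v, log(s0))

  rss_trace <- numeric(0)
  a <- hi - v; b <- lo + u
  frozen <- FALSE
  n_done <- 0L
  converged_early <- FALSE
  best_obj <- Inf
  for (k in seq_len(n_iter)) {
    if (!frozen) {
      cc <- pmin(1, pmax(0, (y - b) / (a - b)))            # Step 1
      # Step 2; the first iteration also tries a full-range start so the
      # solver cannot be trapped by a poor initialization
      refit <- refit_intensities_ml(
        y, par, lo, hi,
        extra_starts = if (k == 1) list(c(0, 0, log((hi - lo) / 4))) else list())
      new_par <- refit$par
      change <- max(abs(new_par[1:2] - par[1:2]))
      # the update must improve the marginal likelihood; once it stops
      # improving the alternation has reached its fixed point
      if (refit$objective >= best_obj - 1e-10) { frozen <- TRUE; change <- 0 }
      else { best_obj <- refit$objective; par <- new_par }
      b <- lo + par[1]; a <- hi - par[2]
      if (a - b <= 1e-6)
        stop("non-identifiable ROI: estimated mu_gm and mu_wm coincide",
             call. = FALSE)
      cc <- pmin(1, pmax(0, (y - b) / (a - b)))
      rss <- sum((y - b - (a - b) * cc)^2)
      if (change < 1e-9) frozen <- TRUE                     # fixed point
    }
    rss_trace <- c(rss_trace, rss)
    n_done <- k
    if (tol > 0 && frozen) { converged_early <- TRUE; break }
    if (tol > 0 && change < tol) { converged_early <- TRUE; break }
  }
  structure(list(
    intensities = tissue_intensities(a, b, sigma = exp(par[3])),
    concentrations = concentration_field(cc),
    rss_trace = rss_trace,
    n_iterations = n_done,
    converged_early = converged_early,
    n_voxels = length(y),
    sigma_rss = sqrt(rss / length(y)),
    data_range = c(lo, hi)
  ), class = "pve_fit")
}

#' @export
print.pve_fit <- function(x, ...) {
  cat(sprintf("<pve_fit> %d voxels, %d iteration(s)%s\n", x$n_voxels,
              x$n_iterations, if (x$converged_early) " (early stop)" else ""))
  cat(sprintf("  mu_gm = %.2f ms, mu_wm = %.2f ms, sigma = %.2f ms\n",
              x$intensities$mu_gm, x$intensities$mu_wm, x$intensities$sigma))
  cat(sprintf("  final RSS = %.4g ms^2, mean c_gm = %.3f\n",
              x$rss_trace[length(x$rss_trace)], mean(x$concentrations$c_gm)))
  invisible(x)
}

#' Fit the partial-volume model to one labelled region of a volume
#'
#' Extracts the region's voxels from the label volume, removes lesion
#' voxels so that only normal-appearing tissue enters the fit, drops
#' non-finite or non-positive T1 values with a logged count, and runs
#' [fit_pve]. The characteristic intensities are global to the region;
#' regions are fitted independently.
#'
#' @param volume A [t1_volume].
#' @param labels A [label_volume] on the same grid.
#' @param region Region name; must be present in the label dictionary.
#' @param lesions Optional [binary_mask] of lesions to exclude.
#' @param config Optional list overriding `init_mu_gm`, `init_mu_wm`,
#'   `n_iter`, `tol` and `min_voxels` (see [default_run_config]).
#' @return A `pve_fit` with additional elements `region`, `subject_id` and
#'   `voxels` (linear indices of the fitted voxels).
#' @export
fit_region <- function(volume, labels, region, lesions = NULL,
                       config = list()) {
  cfg <- utils::modifyList(default_run_config()$pve, config)
  stop_if_grid_mismatch(volume, labels)
  if (!region %in% names(labels$dictionary))
    stop("region '", region, "' not in label dictionary", call. = FALSE)
  lab <- labels$dictionary[[region]]
  idx <- which(labels$labels == lab)
  if (length(idx) == 0) stop("region '", region, "' is empty", call. = FALSE)
  if (!is.null(lesions)) {
    stop_if_grid_mismatch(volume, lesions)
    idx <- idx[!lesions$mask[idx]]
  }
  y <- volume$values[idx]
  ok <- is.finite(y) & y > 0
  if (any(!ok)) {
    message("fit_region: dropping ", sum(!ok),
            " non-finite/non-positive voxel(s) in ", region)
    idx <- idx[ok]; y <- y[ok]
  }
  if (length(idx) < cfg$min_voxels)
    stop("region '", region, "' has ", length(idx),
         " usable voxels, fewer than the minimum of ", cfg$min_voxels,
         call. = FALSE)
  fit <- fit_pve(y, init = tissue_intensities(cfg$init_mu_gm, cfg$init_mu_wm),
                 n_iter = cfg$n_iter, tol = cfg$tol)
  fit$concentrations$voxels <- idx
  fit$voxels <- idx
  fit$region <- region
  fit$subject_id <- volume$subject_id
  fit
}

#' Export a region's GM concentration map as a volume
#'
#' Builds a full-grid map with the fitted GM concentrations at the region's
#' voxels and 0 elsewhere, suitable for writing with [write_t1_volume].
#'
#' @param fit A `pve_fit` returned by [fit_region].
#' @param labels The [label_volume] the fit was made on (provides the grid).
#' @return A [t1_volume]-classed volume whose values are GM fractions.
#' @export
concentration_map <- function(fit, labels) {
  if (is.null(fit$voxels))
    stop("fit carries no voxel indices; use fit_region()", call. = FALSE)
  vals <- array(0, dim = dim(labels$labels))
  vals[fit$voxels] <- fit$concentrations$c_gm
  t1_volume(vals, affine = labels$affine,
            subject_id = if (is.null(fit$subject_id)) NA_character_ else fit$subject_id)
}
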