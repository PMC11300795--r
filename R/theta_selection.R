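#' Default theta grid
#'
#' Zero plus a decade-spaced logarithmic grid from 1e-2 to 1e7 (11 points),
#' covering the range from an unregularised fit to a prior-dominated one.
#'
#' @return Numeric vector of theta values, increasing.
#' @export
default_theta_grid <- function() c(0, 10^(-2:7))

#' Scan the regularisation strength
#'
#' Runs [optimize_weights] for every theta on the grid, warm-starting each
#' solve from the solution at the next-larger theta (the scan proceeds in
#' descending order; large theta starts at the prior, which is its own
#' optimum in the limit). Records the misfit/entropy trade-off curve.
#'
#' @param sel a `voxel_selection`.
#' @param w0 prior weights (default uniform).
#' @param sigma_L2 likelihood noise variance.
#' @param thetas theta grid (each >= 0, default [default_theta_grid()]).
#' @return An object of class `theta_curve`: list with `thetas` (ascending),
#'   `chi2s`, `s_kls`, `neffs`, `weights` (M x n_theta matrix, columns
#'   aligned with `thetas`), `alphas`, `w0`, `selected_index` (NA until
#'   [kneedle_select] is applied).
#' @export
scan_thetas <- function(sel, w0 = NULL, sigma_L2, thetas = default_theta_grid()) {
  if (!length(thetas)) stop("theta grid is empty")
  if (any(thetas < 0)) stop("theta values must be >= 0")
  thetas <- sort(unique(thetas))
  M <- sel$n_models
  if (is.null(w0)) w0 <- rep(1 / M, M)
  n <- length(thetas)
  chi2s <- s_kls <- alphas <- numeric(n)
  W <- matrix(NA_real_, nrow = M, ncol = n)
  g <- NULL
  for (k in rev(seq_len(n))) {
    fit <- tryCatch(
      optimize_weights(sel, w0 = w0, theta = thetas[k], sigma_L2 = sigma_L2,
                       g_init = g),
      error = function(e) stop("theta scan failed at theta = ", thetas[k],
                               ": ", conditionMessage(e)))
    g <- if (M > 1) fit$g[-M] else NULL
    chi2s[k] <- fit$chi2
    s_kls[k] <- fit$s_kl
    alphas[k] <- fit$alpha
    W[, k] <- fit$w
  }
  structure(list(thetas = thetas, chi2s = chi2s, s_kls = s_kls,
                 neffs = exp(-s_kls), weights = W, alphas = alphas, w0 = w0,
                 selected_index = NA_integer_),
            class = "theta_curve")
}

#' @export
print.theta_curve <- function(x, ...) {
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.theta_curve <- function(x, ...) {
  data.frame(theta = x$thetas, chi2 = x$chi2s, s_kl = x$s_kls,
             neff = x$neffs,
             selected = seq_along(x$thetas) == x$selected_index)
}

#' Select theta at the knee of the L-curve (Kneedle)
#'
#' The trade-off curve uses coordinates (S_KL, chi2): decreasing and convex
#' when the scan is well behaved. Both axes are min-max normalised to [0, 1]
#' (making the selection invariant to affine rescaling of either axis); the
#' Kneedle difference curve for a decreasing-convex set is
#' `d = (1 - y) - x`, and the knee is the point maximising `d` - equivalently
#' the point of maximal perpendicular distance from the corner-to-corner
#' chord. If no point rises above the chord (a straight line has `d = 0`
#' everywhere) the fallback picks, among thetas whose chi2 is within 5% of
#' the minimum, the one with the largest effective sample fraction, and
#' flags it.
#'
#' The theta = 0 point is excluded from knee candidacy when its effective
#' sample fraction falls below 1/M (a degenerate overfit that would drag the
#' normalisation).
#'
#' A misfit-band guard backs the geometric knee: the selected point must
#' deliver low misfit in absolute terms, not merely sit at the corner of the
#' normalised curve. When the knee's normalised misfit exceeds `misfit_band`
#' (a fraction of the scan's misfit range above the achievable floor), the
#' selection moves to the strongest-regularisation point inside the band
#' (the largest effective sample fraction among thetas whose chi2 is within
#' the band). Because the guard operates on the min-max normalised misfit it
#' preserves the affine invariance of the selection.
#'
#' @param curve a `theta_curve` with at least 3 points.
#' @param sensitivity Kneedle sensitivity (fixed at 1 for a finite grid; the
#'   maximum of the difference curve is used directly).
#' @param misfit_band fraction of the normalised misfit range that the
#'   selected point may sit above the floor (default 0.01).
#' @return List with `theta`, `index` (into `curve$thetas`), `fallback`
#'   (logical), `guarded` (logical: the misfit-band guard displaced the
#'   geometric knee), `difference` (the Kneedle difference values on the
#'   candidate points).
#' @export
kneedle_select <- function(curve, sensitivity = 1, misfit_band = 0.01) {
  stopifnot(inherits(curve, "theta_curve"))
  n <- length(curve$thetas)
  if (n < 3) stop("knee detection needs at least 3 scanned theta values")
  M <- nrow(curve$weights)
  cand <- seq_len(n)
  degenerate_zero <- curve$thetas == 0 & curve$neffs < 1 / M
  cand <- cand[!degenerate_zero]
  if (length(cand) < 3) cand <- seq_len(n)
  x <- curve$s_kls[cand]
  y <- curve$chi2s[cand]
  ord <- order(x)
  x <- x[ord]; y <- y[ord]; cand <- cand[ord]
  rx <- diff(range(x)); ry <- diff(range(y))
  if (rx <= 0 || ry <= 0) {
    idx <- fallback_theta(curve)
    return(list(theta = curve$thetas[idx], index = idx, fallback = TRUE,
                guarded = FALSE, difference = rep(0, length(cand))))
  }
  xn <- (x - min(x)) / rx
  yn <- (y - min(y)) / ry
  d <- (1 - yn) - xn
  if (max(d) <= 1e-9) {
    idx <- fallback_theta(curve)
    return(list(theta = curve$thetas[idx], index = idx, fallback = TRUE,
                guarded = FALSE, difference = d))
  }
  k <- which.max(d)
  guarded <- FALSE
  if (yn[k] > misfit_band) {
    ## geometric corner sits too far above the misfit floor: take the
    ## most-regularised point (largest Neff) still inside the band
    in_band <- which(yn <= misfit_band)
    if (length(in_band)) {
      k <- in_band[which.max(curve$neffs[cand[in_band]])]
      guarded <- TRUE
    }
  }
  knee <- cand[k]
  list(theta = curve$thetas[knee], index = knee, fallback = FALSE,
       guarded = guarded, difference = d)
}

## Insert log-spaced theta values between the provisional knee and its grid
## neighbours (used by the one-shot knee refinement).
refine_theta_grid <- function(thetas, knee_index, points_per_side = 3) {
  n <- length(thetas)
  extra <- numeric(0)
  span <- function(a, b) {
    if (a <= 0) return(numeric(0))
    exp(seq(log(a), log(b), length.out = points_per_side + 2))[-c(1, points_per_side + 2)]
  }
  if (knee_index > 1) extra <- c(extra, span(thetas[knee_index - 1], thetas[knee_index]))
  if (knee_index < n) extra <- c(extra, span(thetas[knee_index], thetas[knee_index + 1]))
  sort(unique(c(thetas, extra)))
}

fallback_theta <- function(curve) {
  ok <- curve$chi2s <= 1.05 * min(curve$chi2s)
  idx <- which(ok)
  idx[which.max(curve$neffs[idx])]
}

#' Write a theta curve as TSV
#'
#' @param curve a `theta_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_theta_curve_tsv <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
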