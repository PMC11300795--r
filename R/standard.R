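#' Standard-mode Bayesian reweighting against a density map
#'
#' The full single-round pipeline: simulate per-member model maps on the
#' reference grid (unless supplied), select the reweighting voxels, estimate
#' the likelihood noise variance from the solvent region (unless supplied),
#' scan theta, and pick the knee of the L-curve. The reference map should
#' already be normalised (see [normalize_map]); model maps are simulated at
#' kernel width `sigma` (default 0.225 x resolution) or scanned over
#' `sigma_grid`.
#'
#' @param ref reference [density_map], normalised.
#' @param ensemble an [ensemble_spec] (needed unless `model_maps` given).
#' @param model_maps optional pre-computed list of model [density_map]s on
#'   the reference grid (skips forward-model simulation).
#' @param resolution nominal resolution (Angstrom), sets the default sigma.
#' @param sigma model-map kernel width; default `0.225 * resolution`.
#' @param sigma_grid optional vector of candidate widths; when given, the
#'   width is selected by [scan_sigma_kernel] and `sigma` is ignored.
#' @param noise a [noise_model] for the reference threshold; when `NULL` and
#'   no `ref_threshold` is given, the threshold is `3 * sqrt(sigma_L2)` with
#'   the variance estimated from the solvent region.
#' @param ref_threshold optional absolute reference-density threshold.
#' @param w0 prior weights (default uniform).
#' @param thetas theta grid.
#' @param sigma_L2 likelihood noise variance; estimated from the solvent
#'   region when `NULL`.
#' @param refine_knee a decade-spaced theta grid localises the L-curve knee
#'   only to within a factor of 10; when TRUE (default) the scan is repeated
#'   once with extra log-spaced theta values inserted between the
#'   provisional knee and its two grid neighbours, and the knee re-detected
#'   on the enriched curve.
#' @return An object of class `reweight_result`: `weights`, `w0`, `theta`,
#'   `alpha`, `sigma_kernel`, `sigma_L2`, `chi2`, `s_kl`, `neff`,
#'   `theta_curve`, `knee_fallback`, `cc` / `prior_cc` (selection-restricted
#'   Pearson correlation of posterior/prior average map with the reference),
#'   `cc_box` / `prior_cc_box` (whole-box), `selection`, `model_maps`,
#'   `labels`.
#' @export
reweight_standard <- function(ref, ensemble = NULL, model_maps = NULL,
                              resolution, sigma = 0.225 * resolution,
                              sigma_grid = NULL, noise = NULL,
                              ref_threshold = NULL, w0 = NULL,
                              thetas = default_theta_grid(),
                              sigma_L2 = NULL, refine_knee = TRUE) {
  stopifnot(inherits(ref, "density_map"))
  labels <- if (!is.null(ensemble)) ensemble$labels
            else sprintf("model_%03d", seq_along(model_maps))

  if (!is.null(sigma_grid)) {
    scan <- scan_sigma_kernel(ensemble, ref, sigma_grid, noise = noise,
                              ref_threshold = ref_threshold, w0 = w0,
                              thetas = thetas)
    sigma <- scan$sigma
    model_maps <- scan$model_maps
    sel <- scan$selection
    sL2 <- scan$sigma_L2
    curve <- scan$curve
    knee <- scan$knee
  } else {
    if (is.null(model_maps)) {
      if (is.null(ensemble)) stop("supply an ensemble or pre-computed model maps")
      model_maps <- lapply(ensemble$structures, simulate_model_map,
                           grid_of = ref, sigma = sigma)
    }
    sL2 <- if (is.null(sigma_L2)) estimate_sigma_L(ref, model_maps) else sigma_L2
    if (is.null(ref_threshold) && is.null(noise))
      ref_threshold <- 3 * sqrt(sL2)
    sel <- select_voxels(ref, model_maps, noise = noise,
                         ref_threshold = ref_threshold, sigma_kernel = sigma)
    curve <- scan_thetas(sel, w0 = w0, sigma_L2 = sL2, thetas = thetas)
    knee <- kneedle_select(curve)
  }
  if (refine_knee && !knee$fallback) {
    enriched <- refine_theta_grid(curve$thetas, knee$index)
    if (length(enriched) > length(curve$thetas)) {
      curve <- scan_thetas(sel, w0 = w0, sigma_L2 = sL2, thetas = enriched)
      knee <- kneedle_select(curve)
    }
  }
  curve$selected_index <- knee$index
  w <- curve$weights[, knee$index]
  w0_used <- curve$w0
  a <- curve$alphas[knee$index]

  post_map <- average_map(model_maps, w)
  prior_map <- average_map(model_maps, w0_used)
  r_idx <- sel$r_indices
  rv <- as.vector(ref$values)
  cc_sel <- stats::cor(rv[r_idx], as.vector(post_map$values)[r_idx])
  prior_cc_sel <- stats::cor(rv[r_idx], as.vector(prior_map$values)[r_idx])
  cc_box <- stats::cor(rv, as.vector(post_map$values))
  prior_cc_box <- stats::cor(rv, as.vector(prior_map$values))

  structure(list(weights = w, w0 = w0_used, theta = knee$theta,
                 alpha = a, sigma_kernel = sel$sigma_kernel, sigma_L2 = sL2,
                 chi2 = curve$chi2s[knee$index], s_kl = curve$s_kls[knee$index],
                 neff = curve$neffs[knee$index], theta_curve = curve,
                 knee_fallback = knee$fallback,
                 cc = cc_sel, prior_cc = prior_cc_sel,
                 cc_box = cc_box, prior_cc_box = prior_cc_box,
                 selection = sel, model_maps = model_maps, labels = labels),
            class = "reweight_result")
}

#' @export
print.reweight_result <- function(x, ...) {
  cat("Bayesian map reweighting (standard mode)\n")
  cat(sprintf("  M = %d members, N = %d voxels, kernel sigma = %.3g A\n",
              length(x$weights), x$selection$n_voxels, x$sigma_kernel))
  cat(sprintf("  selected theta = %g%s, alpha = %.4g, sigma_L2 = %.4g\n",
              x$theta, if (x$knee_fallback) " (fallback)" else "", x$alpha,
              x$sigma_L2))
  cat(sprintf("  chi2 = %.4g, S_KL = %.4g nats, Neff = %.3f\n",
              x$chi2, x$s_kl, x$neff))
  cat(sprintf("  map CC (selection): prior %.4f -> posterior %.4f\n",
              x$prior_cc, x$cc))
  invisible(x)
}

#' Posterior ensemble-average map of a reweighting result
#'
#' @param result a `reweight_result`.
#' @return A [density_map].
#' @export
posterior_map <- function(result) {
  average_map(result$model_maps, result$weights)
}

#' Write a result bundle as JSON
#'
#' Records the selected hyperparameters and summary statistics (theta,
#' alpha, sigma, sigma_L2, chi2, S_KL, Neff, CC) plus the full theta curve.
#'
#' @param result a `reweight_result`.
#' @param path output JSON path.
#' @param extra optional named list merged into the bundle (e.g. config).
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path, extra = list()) {
  bundle <- c(list(theta = result$theta, alpha = result$alpha,
                   sigma_kernel = result$sigma_kernel,
                   sigma_L2 = result$sigma_L2, chi2 = result$chi2,
                   s_kl = result$s_kl, neff = result$neff,
                   cc = result$cc, cc_box = result$cc_box,
                   prior_cc = result$prior_cc,
                   knee_fallback = result$knee_fallback,
                   theta_curve = as.data.frame(result$theta_curve),
                   weights = data.frame(member_id = result$labels,
                                        w0 = result$w0, w = result$weights)),
              extra)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
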