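#' Kullback-Leibler divergence between weight vectors
#'
#' `S_KL = sum_i w_i ln(w_i / w0_i)`, the entropic penalty keeping the
#' posterior weights close to the prior. Zero weights contribute 0 via the
#' limit x ln x -> 0.
#'
#' @param w,w0 normalised, non-negative weight vectors of equal length.
#' @return S_KL in nats (>= 0; 0 iff `w == w0`).
#' @export
kl_divergence <- function(w, w0) {
  if (length(w) != length(w0)) stop("weight vectors must have equal length")
  if (abs(sum(w) - 1) > 1e-8 || abs(sum(w0) - 1) > 1e-8)
    stop("weights must be normalised (|sum - 1| <= 1e-8)")
  if (any(w < 0) || any(w0 <= 0)) stop("weights must be positive (prior strictly)")
  nz <- w > 0
  sum(w[nz] * log(w[nz] / w0[nz]))
}

#' Effective sample fraction
#'
#' `Neff = exp(-S_KL)`, the fraction of the ensemble effectively carrying
#' weight after reweighting; 1 when the posterior equals the prior.
#'
#' @param s_kl KL divergence in nats (>= 0).
#' @return Fraction in (0, 1].
#' @export
effective_sample_size <- function(s_kl) {
  if (s_kl < 0) stop("S_KL must be >= 0")
  exp(-s_kl)
}

## Weighted model density over the selection: rho_bar = R %*% w.
weighted_density <- function(sel, w) {
  as.vector(sel$model_density %*% w)
}

#' Map misfit chi-squared
#'
#' `chi2 = sum_n (rho0_n - alpha * sum_i w_i rho^i_n)^2 / sigma_L2`. This is
#' the reported misfit (no factor 1/2); the posterior objective uses half of
#' it.
#'
#' @param sel a `voxel_selection`.
#' @param w normalised weights (length M).
#' @param alpha map scale factor.
#' @param sigma_L2 likelihood noise variance (> 0).
#' @return Non-negative scalar.
#' @export
chi2 <- function(sel, w, alpha, sigma_L2) {
  if (sigma_L2 <= 0) stop("sigma_L2 must be positive")
  r <- sel$ref_density - alpha * weighted_density(sel, w)
  if (any(!is.finite(r))) stop("non-finite densities in the selection")
  sum(r^2) / sigma_L2
}

#' Closed-form optimal map scale
#'
#' The least-squares scale `alpha = (rho0 . rho_bar) / (rho_bar . rho_bar)`
#' minimising chi2 over alpha at fixed weights. Unconstrained in sign; a
#' warning is emitted when alpha <= 0 (usually a sign of a pathological
#' selection).
#'
#' @param sel a `voxel_selection`.
#' @param w normalised weights.
#' @return Scalar alpha.
#' @export
optimal_alpha <- function(sel, w) {
  rb <- weighted_density(sel, w)
  den <- sum(rb^2)
  if (den <= 0) stop("weighted model density is identically zero")
  a <- sum(sel$ref_density * rb) / den
  if (a <= 0) warning("optimal map scale alpha <= 0; check the voxel selection")
  a
}

## Weights from gauge-fixed log-weight parameters: g has length M with
## g[M] == 0; w_i = w0_i exp(g_i) / sum_j w0_j exp(g_j).
weights_from_g <- function(g, w0) {
  u <- log(w0) + g
  u <- u - max(u)
  e <- exp(u)
  e / sum(e)
}

#' Negative log-posterior over log-weights
#'
#' Evaluates `theta * S_KL(w(g)) + chi2(w(g), alpha*(w(g))) / 2` with the map
#' scale alpha profiled out analytically at every evaluation, together with
#' the exact gradient with respect to the free log-weight parameters
#' `g[1..M-1]` (gauge `g[M] = 0`). The gradient uses the envelope theorem:
#' alpha minimises the data term, so its implicit dependence on g drops out.
#'
#' @param g_free numeric length M-1 (free log-weights; the full g appends 0).
#' @param theta regularisation strength (>= 0).
#' @param sel a `voxel_selection`.
#' @param w0 prior weights (normalised, positive, length M).
#' @param sigma_L2 likelihood noise variance.
#' @return List with `value`, `gradient` (length M-1), `w`, `alpha`.
#' @export
neg_log_posterior <- function(g_free, theta, sel, w0, sigma_L2) {
  if (theta < 0) stop("theta must be >= 0")
  if (any(!is.finite(g_free))) stop("non-finite log-weights")
  M <- length(w0)
  g <- c(g_free, 0)
  w <- weights_from_g(g, w0)
  rb <- weighted_density(sel, w)
  den <- sum(rb^2)
  alpha <- if (den > 0) sum(sel$ref_density * rb) / den else 0
  r <- sel$ref_density - alpha * rb
  ## weight floor: w ln w -> 0 as w -> 0; clamp keeps logs finite when a
  ## weight underflows to double-precision zero
  log_ratio <- log(pmax(w, 1e-300) / w0)
  s_kl <- sum(w * log_ratio)
  value <- theta * s_kl + sum(r^2) / (2 * sigma_L2)
  ## d/dw_i of the objective (alpha fixed at its optimum):
  dW <- theta * (log_ratio + 1) -
    (alpha / sigma_L2) * as.vector(crossprod(sel$model_density, r))
  ## chain rule through the softmax: df/dg_i = w_i (dW_i - sum_k w_k dW_k)
  dG <- w * (dW - sum(w * dW))
  list(value = value, gradient = dG[-M], w = w, alpha = alpha)
}

#' Optimise ensemble weights at fixed theta
#'
#' Quasi-Newton (BFGS) minimisation of the negative log-posterior over
#' gauge-fixed log-weights, started from the prior (`g = 0`) unless a warm
#' start is given. Weights remain strictly positive by construction of the
#' log-weight parameterisation.
#'
#' @param sel a `voxel_selection`.
#' @param w0 prior weights (normalised, positive); default uniform.
#' @param theta regularisation strength (>= 0).
#' @param sigma_L2 likelihood noise variance.
#' @param g_init optional warm-start free log-weights (length M-1).
#' @param tol relative gradient-infinity-norm tolerance for convergence.
#' @param maxit maximum BFGS iterations.
#' @return List with `w`, `w0`, `g` (full, gauge-fixed), `alpha`, `chi2`
#'   (reported, no 1/2), `s_kl`, `neff`, `value`, `converged`.
#' @export
optimize_weights <- function(sel, w0 = NULL, theta, sigma_L2,
                             g_init = NULL, tol = 1e-8, maxit = 10000) {
  M <- sel$n_models
  if (is.null(w0)) w0 <- rep(1 / M, M)
  if (length(w0) != M) stop("prior weight length must equal the model count")
  if (abs(sum(w0) - 1) > 1e-8 || any(w0 <= 0))
    stop("prior weights must be normalised and strictly positive")
  if (M == 1L) {
    a <- optimal_alpha(sel, 1)
    return(list(w = 1, w0 = 1, g = 0, alpha = a,
                chi2 = chi2(sel, 1, a, sigma_L2), s_kl = 0, neff = 1,
                value = chi2(sel, 1, a, sigma_L2) / 2, converged = TRUE))
  }
  if (is.null(g_init)) g_init <- numeric(M - 1)
  fn <- function(g) neg_log_posterior(g, theta, sel, w0, sigma_L2)$value
  gr <- function(g) neg_log_posterior(g, theta, sel, w0, sigma_L2)$gradient
  par <- g_init
  converged <- FALSE
  f_prev <- Inf
  for (attempt in 1:6) {
    fit <- stats::optim(par, fn, gr, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-15))
    par <- fit$par
    ev <- neg_log_posterior(par, theta, sel, w0, sigma_L2)
    if (any(!is.finite(ev$gradient)))
      stop("non-finite gradient during weight optimisation at theta = ", theta)
    if (max(abs(ev$gradient)) <= tol * max(1, abs(ev$value))) {
      converged <- TRUE
      break
    }
    ## near theta = 0 the optimum can sit at the simplex boundary, which is
    ## at infinity in log-weight space: the gradient never vanishes there,
    ## but the objective (and the weights) stop moving; accept stationarity
    ## of the objective across a BFGS restart as convergence
    if (attempt > 1 && f_prev - ev$value <= 1e-8 * max(1, abs(ev$value))) {
      converged <- TRUE
      break
    }
    f_prev <- ev$value
  }
  if (!converged) {
    stop("weight optimisation did not converge (|grad|_inf = ",
         signif(max(abs(ev$gradient)), 3), ", objective = ",
         signif(ev$value, 6), ") at theta = ", theta)
  }
  w <- ev$w
  a <- ev$alpha
  s_kl <- max(0, kl_divergence(w, w0))   # guard float negatives at w ~ w0
  list(w = w, w0 = w0, g = c(par, 0), alpha = a,
       chi2 = chi2(sel, w, a, sigma_L2), s_kl = s_kl,
       neff = effective_sample_size(s_kl), value = ev$value,
       converged = converged)
}

#' Scan candidate kernel widths
#'
#' The model-map kernel width sigma is a nuisance parameter handled by a
#' discrete grid scan: for each candidate the model-density matrix is
#' rebuilt, the full theta scan run, and the knee-selected posterior misfit
#' recorded. The sigma with the smallest posterior chi2 wins; ties go to the
#' smaller sigma.
#'
#' @param ensemble an [ensemble_spec].
#' @param ref reference [density_map] (already normalised).
#' @param sigma_grid candidate kernel widths (Angstrom).
#' @param noise a [noise_model] for the reference threshold, or NULL with
#'   `ref_threshold`.
#' @param ref_threshold optional absolute reference threshold.
#' @param w0 prior weights (default uniform).
#' @param thetas theta grid (default [default_theta_grid()]).
#' @param table kernel table.
#' @return List with `sigma` (the winner), `selection` (its
#'   `voxel_selection`), `chi2s` (per candidate), `sigmas` (the grid,
#'   sorted), `model_maps` (for the winning sigma).
#' @export
scan_sigma_kernel <- function(ensemble, ref, sigma_grid, noise = NULL,
                              ref_threshold = NULL, w0 = NULL,
                              thetas = default_theta_grid(),
                              table = kernel_table()) {
  if (!length(sigma_grid)) stop("empty sigma grid")
  sigmas <- sort(unique(sigma_grid))
  best <- NULL
  chi2s <- numeric(length(sigmas))
  for (k in seq_along(sigmas)) {
    s <- sigmas[k]
    maps <- lapply(ensemble$structures, simulate_model_map,
                   grid_of = ref, sigma = s, table = table)
    sel <- select_voxels(ref, maps, noise = noise,
                         ref_threshold = ref_threshold, sigma_kernel = s)
    sL2 <- estimate_sigma_L(ref, maps)
    curve <- scan_thetas(sel, w0 = w0, sigma_L2 = sL2, thetas = thetas)
    knee <- kneedle_select(curve)
    chi2s[k] <- curve$chi2s[knee$index]
    if (is.null(best) || chi2s[k] < best$chi2 - 1e-12) {
      best <- list(sigma = s, selection = sel, chi2 = chi2s[k],
                   model_maps = maps, sigma_L2 = sL2, curve = curve,
                   knee = knee)
    }
  }
  list(sigma = best$sigma, selection = best$selection, chi2s = chi2s,
       sigmas = sigmas, model_maps = best$model_maps,
       sigma_L2 = best$sigma_L2, curve = best$curve, knee = best$knee)
}

#' Write weights as TSV
#'
#' @param labels member ids.
#' @param w0,w prior and posterior weights.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weights_tsv <- function(labels, w0, w, path) {
  utils::write.table(
    data.frame(member_id = labels, w0 = w0, w = w),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
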