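test_that("KL divergence matches closed forms and direct summation", {
  w0 <- rep(0.25, 4)
  expect_equal(kl_divergence(w0, w0), 0)
  ## nearly-degenerate two-state: S_KL -> ln 2
  eps <- 1e-12
  expect_equal(kl_divergence(c(1 - eps, eps), c(0.5, 0.5)), log(2),
               tolerance = 1e-9)
  ## exact concentration handles the x ln x -> 0 limit
  expect_equal(kl_divergence(c(1, 0, 0, 0, 0), rep(0.2, 5)), log(5))
  set.seed(2)
  for (i in 1:5) {
    w <- runif(5); w <- w / sum(w)
    v <- runif(5); v <- v / sum(v)
    direct <- sum(sapply(1:5, function(k) w[k] * log(w[k] / v[k])))
    expect_equal(kl_divergence(w, v), direct)
    expect_gte(kl_divergence(w, v), 0)
  }
  expect_error(kl_divergence(c(0.5, 0.4), c(0.5, 0.5)), "normalised")
})

test_that("effective sample fraction is exp(-S_KL)", {
  expect_equal(effective_sample_size(0), 1)
  expect_equal(effective_sample_size(log(2)), 0.5)
  ## all weight on 1 of 10 uniform-prior members
  s <- kl_divergence(c(1, rep(0, 9)), rep(0.1, 10))
  expect_equal(effective_sample_size(s), 0.1)
  expect_error(effective_sample_size(-0.1), ">= 0")
})

test_that("chi2 follows the voxel-residual formula", {
  sel <- toy_selection(N = 2, M = 1)
  sel$ref_density <- c(1, 0)
  sel$model_density <- matrix(c(0.5, 0.5), ncol = 1)
  expect_equal(chi2(sel, 1, alpha = 1, sigma_L2 = 1), 0.5)
  expect_equal(chi2(sel, 1, alpha = 1, sigma_L2 = 2), 0.25)   # doubling halves
  ## perfect single-model fit
  sel$model_density <- matrix(sel$ref_density, ncol = 1)
  expect_equal(chi2(sel, 1, alpha = 1, sigma_L2 = 0.3), 0)
  expect_error(chi2(sel, 1, 1, 0), "positive")
})

test_that("profiled alpha equals the least-squares closed form", {
  sel <- toy_selection(N = 10, M = 3, seed = 5)
  w <- c(0.2, 0.5, 0.3)
  sel$ref_density <- 2 * as.vector(sel$model_density %*% w)
  expect_equal(optimal_alpha(sel, w), 2)
  ## orthogonal reference: alpha = 0 (with a warning)
  sel2 <- toy_selection(N = 2, M = 1)
  sel2$model_density <- matrix(c(1, 0), ncol = 1)
  sel2$ref_density <- c(0, 1)
  expect_warning(a0 <- optimal_alpha(sel2, 1), "alpha")
  expect_equal(a0, 0)
  ## random instance: matches a 1-D numeric minimisation of chi2
  sel3 <- toy_selection(N = 10, M = 2, seed = 9)
  w3 <- c(0.6, 0.4)
  num <- optimize(function(a) chi2(sel3, w3, a, 1), c(-10, 10), tol = 1e-12)
  expect_equal(optimal_alpha(sel3, w3), num$minimum, tolerance = 1e-8)
})

test_that("negative log-posterior value and gradient are exact", {
  sel <- toy_selection(N = 6, M = 4, seed = 3)
  w0 <- c(0.1, 0.2, 0.3, 0.4)
  ## g = 0: KL term vanishes, value = chi2(w0)/2 for any theta
  for (th in c(0, 1, 1e3)) {
    ev <- neg_log_posterior(numeric(3), th, sel, w0, sigma_L2 = 0.5)
    a <- optimal_alpha(sel, w0)
    expect_equal(ev$value, chi2(sel, w0, a, 0.5) / 2)
  }
  ## gradient matches central finite differences at 10 random points
  set.seed(7)
  for (i in 1:10) {
    g <- rnorm(3, 0, 1.5)
    th <- runif(1, 0, 50)
    ev <- neg_log_posterior(g, th, sel, w0, sigma_L2 = 0.5)
    h <- 1e-6
    fd <- sapply(1:3, function(k) {
      gp <- g; gp[k] <- g[k] + h
      gm <- g; gm[k] <- g[k] - h
      (neg_log_posterior(gp, th, sel, w0, 0.5)$value -
         neg_log_posterior(gm, th, sel, w0, 0.5)$value) / (2 * h)
    })
    expect_equal(ev$gradient, fd, tolerance = 1e-5)
  }
  ## theta = 0: value independent of the prior at fixed weights
  w_target <- c(0.4, 0.3, 0.2, 0.1)
  g_for <- function(w, w0) { g <- log(w / w0); g - g[4] }
  v1 <- neg_log_posterior(g_for(w_target, w0)[1:3], 0, sel, w0, 0.5)$value
  w0b <- c(0.25, 0.25, 0.25, 0.25)
  v2 <- neg_log_posterior(g_for(w_target, w0b)[1:3], 0, sel, w0b, 0.5)$value
  expect_equal(v1, v2, tolerance = 1e-12)
  expect_error(neg_log_posterior(c(NA, 0, 0), 1, sel, w0, 0.5), "non-finite")
  expect_error(neg_log_posterior(numeric(3), -1, sel, w0, 0.5), ">= 0")
})

test_that("weight optimisation handles the forced and prior-dominated limits", {
  sel1 <- toy_selection(N = 5, M = 1, seed = 4)
  fit1 <- optimize_weights(sel1, theta = 3, sigma_L2 = 1)
  expect_equal(fit1$w, 1)
  expect_equal(fit1$neff, 1)
  ## theta >> data term: posterior returns to the (non-uniform) prior
  sel <- toy_selection(N = 6, M = 4, seed = 3)
  w0 <- c(0.1, 0.2, 0.3, 0.4)
  fit <- optimize_weights(sel, w0 = w0, theta = 1e9, sigma_L2 = 1)
  expect_lt(max(abs(fit$w - w0)), 1e-3)
  expect_error(optimize_weights(sel, w0 = c(1, 1, 1, 1), theta = 1, sigma_L2 = 1),
               "normalised")
})

test_that("two-model unregularised fit matches a dense 1-D grid search", {
  ## model 1 equals the reference, model 2 orthogonal to it
  sel <- toy_selection(N = 4, M = 2)
  sel$ref_density <- c(1, 1, 0, 0)
  sel$model_density <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  fit <- optimize_weights(sel, theta = 0, sigma_L2 = 0.01)
  expect_gt(fit$w[1], 0.99)
  ## brute force over w1 on a 1e-4 grid with profiled alpha
  grid <- seq(1e-4, 1 - 1e-4, by = 1e-4)
  obj <- sapply(grid, function(w1) {
    w <- c(w1, 1 - w1)
    rb <- as.vector(sel$model_density %*% w)
    a <- sum(sel$ref_density * rb) / sum(rb^2)
    sum((sel$ref_density - a * rb)^2) / (2 * 0.01)
  })
  w1_star <- grid[which.min(obj)]
  expect_equal(fit$w[1], w1_star, tolerance = 1e-3)
})

test_that("optimiser matches a simplex grid search for M = 3", {
  sel <- toy_selection(N = 8, M = 3, seed = 12)
  th <- 5
  fit <- optimize_weights(sel, theta = th, sigma_L2 = 0.05)
  ## dense simplex enumeration (step 0.002), vectorised
  step <- 0.002
  w1 <- seq(step, 1 - step, by = step)
  grid <- expand.grid(w1 = w1, w2 = w1)
  grid <- grid[grid$w1 + grid$w2 < 1 - step / 2, ]
  W <- rbind(grid$w1, grid$w2, 1 - grid$w1 - grid$w2)
  RB <- sel$model_density %*% W                     # N x K
  alphas <- colSums(RB * sel$ref_density) / colSums(RB^2)
  resid2 <- colSums((sel$ref_density - sweep(RB, 2, alphas, `*`))^2)
  skl <- colSums(W * log(W / (1 / 3)))
  obj <- th * skl + resid2 / (2 * 0.05)
  w_star <- W[, which.min(obj)]
  expect_lt(max(abs(fit$w - w_star)), 1e-3 + step)
  ## profiled alpha at the optimum equals the closed form
  expect_equal(fit$alpha, optimal_alpha(sel, fit$w))
})

test_that("theta scan produces a monotone trade-off curve", {
  sel <- toy_selection(N = 10, M = 5, seed = 21)
  curve <- scan_thetas(sel, sigma_L2 = 0.02)
  expect_equal(length(curve$thetas), 11)            # {0} U 10^(-2..7)
  expect_true(all(diff(curve$s_kls) <= 1e-8))       # S_KL non-increasing in theta
  expect_true(all(diff(curve$chi2s) >= -1e-6))      # chi2 non-decreasing
  expect_equal(curve$neffs, exp(-curve$s_kls))
  ## weights columns normalised and positive
  expect_true(all(curve$weights > 0))
  expect_equal(colSums(curve$weights), rep(1, 11))
  ## single-point grid
  c0 <- scan_thetas(sel, sigma_L2 = 0.02, thetas = 0)
  expect_length(c0$thetas, 1)
  expect_error(scan_thetas(sel, sigma_L2 = 0.02, thetas = numeric(0)), "empty")
})

test_that("duplicate ensemble members leave the misfit curve unchanged", {
  sel2 <- toy_selection(N = 8, M = 2, seed = 31)
  ## duplicate model 1: M = 3 with uniform prior == M = 2 with prior (2/3, 1/3)
  sel3 <- sel2
  sel3$model_density <- cbind(sel2$model_density[, 1], sel2$model_density)
  sel3$n_models <- 3L
  thetas <- c(0, 1, 100)
  c_dup <- scan_thetas(sel3, sigma_L2 = 0.05, thetas = thetas)
  c_merged <- scan_thetas(sel2, w0 = c(2 / 3, 1 / 3), sigma_L2 = 0.05,
                          thetas = thetas)
  expect_equal(c_dup$chi2s, c_merged$chi2s, tolerance = 1e-6)
})

test_that("kernel-width scan recovers the generating width", {
  ens <- make_two_state_ensemble(n_residues = 12, M = 4, jitter_sd = 0.2,
                                 seed = 2)
  sig_star <- 0.225 * 6
  grid <- cryoreweight:::ensemble_grid(ens, 6, 2, 10)
  maps <- lapply(ens$structures, simulate_model_map, grid_of = grid,
                 sigma = sig_star)
  ref <- add_noise(normalize_map(average_map(maps, rep(0.25, 4))),
                   noise_model(0.01, sd = 0.01, seed = 3))
  scan <- scan_sigma_kernel(ens, ref, c(sig_star / 2, sig_star, 2 * sig_star),
                            noise = noise_model(0.01, sd = 0.01, seed = 3))
  expect_equal(scan$sigma, sig_star)
  ## order invariance and single-value grid
  scan2 <- scan_sigma_kernel(ens, ref, c(2 * sig_star, sig_star, sig_star / 2),
                             noise = noise_model(0.01, sd = 0.01, seed = 3))
  expect_equal(scan2$sigma, scan$sigma)
  one <- scan_sigma_kernel(ens, ref, 1.1,
                           noise = noise_model(0.01, sd = 0.01, seed = 3))
  expect_equal(one$sigma, 1.1)
})

test_that("weights export as TSV", {
  p <- withr::local_tempfile(fileext = ".tsv")
  write_weights_tsv(c("a", "b"), c(0.5, 0.5), c(0.9, 0.1), p)
  tab <- read.delim(p)
  expect_equal(tab$w, c(0.9, 0.1))
  expect_equal(tab$member_id, c("a", "b"))
})
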