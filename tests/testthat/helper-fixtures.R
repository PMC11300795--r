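# Shared fixtures built in code. The benchmark cache avoids re-simulating
# the 100-member model-map stacks across test files.

rand_map <- function(d = c(4, 4, 4), seed = 1, origin = c(0, 0, 0), voxel = 1.5) {
  set.seed(seed)
  density_map(array(runif(prod(d)), dim = d), origin = origin, voxel_size = voxel)
}

one_atom_structure <- function(pos = c(0, 0, 0), element = "C") {
  ens_structure(matrix(pos, ncol = 3), elements = element, label = "atom")
}

## tiny reweighting instance: N voxels, M models, reproducible
toy_selection <- function(N = 6, M = 4, seed = 1) {
  set.seed(seed)
  R <- matrix(runif(N * M, 0, 1), nrow = N)
  ref <- as.vector(R %*% rep(1 / M, M)) + rnorm(N, 0, 0.05)
  ref[ref < 0] <- 0
  structure(list(indices = 0:(N - 1), r_indices = seq_len(N),
                 ref_density = ref, model_density = R,
                 sigma_kernel = 1, n_voxels = N, n_models = M,
                 model_sds = apply(R, 2, sd)),
            class = "voxel_selection")
}

## hand-built theta_curve for knee-detection tests
synthetic_curve <- function(s_kls, chi2s, M = 2) {
  n <- length(s_kls)
  structure(list(thetas = seq_len(n), chi2s = chi2s, s_kls = s_kls,
                 neffs = exp(-s_kls),
                 weights = matrix(1 / M, nrow = M, ncol = n),
                 alphas = rep(1, n), w0 = rep(1 / M, M),
                 selected_index = NA_integer_),
            class = "theta_curve")
}

## memoised benchmark ensembles + model maps (expensive to build)
.bench_cache <- new.env(parent = emptyenv())

cached_two_state <- function() {
  if (is.null(.bench_cache$two_state)) {
    ens <- make_two_state_ensemble(M = 100, seed = 11)
    grid <- cryoreweight:::ensemble_grid(ens, 6, 2, 12)
    maps <- lapply(ens$structures, simulate_model_map, grid_of = grid,
                   sigma = 0.225 * 6)
    .bench_cache$two_state <- list(ens = ens, maps = maps)
  }
  .bench_cache$two_state
}

cached_continuous <- function() {
  if (is.null(.bench_cache$continuous)) {
    ens <- make_continuous_ensemble(M = 100, seed = 7)
    grid <- cryoreweight:::ensemble_grid(ens, 6, 2, 12)
    maps <- lapply(ens$structures, simulate_model_map, grid_of = grid,
                   sigma = 0.225 * 6)
    .bench_cache$continuous <- list(ens = ens, maps = maps)
  }
  .bench_cache$continuous
}
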