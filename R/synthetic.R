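## Synthetic heterogeneity benchmarks with ground-truth weights.
##
## The generators build toy pseudo-atomic structures (a two-domain hinged
## polymer) so no coordinate download is needed; real PDB/mmCIF inputs go
## through read_structures() instead. Every generator is a pure function of
## its seed.

## Backbone template: two compact helical domains joined at a hinge residue.
## Domain B is rotated about the hinge by `angle` (radians) to open/close.
hinged_polymer <- function(n_residues, angle) {
  half <- n_residues %/% 2
  helix <- function(n, phase = 0) {
    t <- seq_len(n)
    cbind(7 * cos(0.6 * t + phase), 7 * sin(0.6 * t + phase), 2.2 * t)
  }
  a <- helix(half)
  hinge <- a[half, ]
  b0 <- helix(n_residues - half, phase = pi / 3)
  ## place domain B beyond the hinge, pointing away from domain A
  b0 <- sweep(b0, 2, b0[1, ]) # start at origin
  b <- sweep(b0, 2, hinge + c(6, 0, 4), `+`)
  ## hinge rotation about the y axis through the hinge point
  cs <- cos(angle); sn <- sin(angle)
  R <- matrix(c(cs, 0, sn, 0, 1, 0, -sn, 0, cs), 3, 3, byrow = TRUE)
  b <- sweep(sweep(b, 2, hinge) %*% t(R), 2, hinge, `+`)
  rbind(a, b)
}

polymer_structure <- function(xyz, label) {
  n <- nrow(xyz)
  ens_structure(xyz, elements = rep("C", n), atom_names = rep("CA", n),
                resid = seq_len(n), chain = rep("A", n), label = label)
}

#' Two-state toy ensemble (discrete heterogeneity)
#'
#' Emulates an open/closed conformational pair: a two-domain hinged polymer
#' whose end states differ by a hinge rotation, with half the members
#' jittered around each end state. With the default hinge angle the
#' end-state RMSD exceeds 4 Angstrom, so the states are separable in maps
#' down to ~6 Angstrom resolution. Member labels record the source state
#' ("open"/"closed").
#'
#' @param n_residues residues in the polymer (one CA pseudo-atom each).
#' @param hinge_angle hinge rotation (radians) between the end states.
#' @param M ensemble size (even).
#' @param jitter_sd per-coordinate Gaussian jitter (Angstrom).
#' @param seed RNG seed.
#' @return An [ensemble_spec]; attribute `states` holds the two clean end
#'   states.
#' @export
make_two_state_ensemble <- function(n_residues = 30, hinge_angle = 0.9,
                                    M = 100, jitter_sd = 0.4, seed = 1L) {
  if (M %% 2 != 0) stop("M must be even (half per state)")
  if (n_residues < 4) stop("need at least 4 residues")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  open_xyz <- hinged_polymer(n_residues, 0)
  closed_xyz <- hinged_polymer(n_residues, hinge_angle)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  jitter <- function(xyz) xyz + matrix(stats::rnorm(length(xyz), 0, jitter_sd),
                                       ncol = 3)
  structs <- vector("list", M)
  labels <- character(M)
  for (i in seq_len(M / 2)) {
    structs[[i]] <- polymer_structure(jitter(open_xyz), sprintf("open_%03d", i))
    labels[i] <- "open"
  }
  for (i in seq_len(M / 2)) {
    structs[[M / 2 + i]] <-
      polymer_structure(jitter(closed_xyz), sprintf("closed_%03d", i))
    labels[M / 2 + i] <- "closed"
  }
  ens <- ensemble_spec(structs, labels = labels)
  attr(ens, "states") <- list(open = polymer_structure(open_xyz, "open_state"),
                              closed = polymer_structure(closed_xyz, "closed_state"))
  ens
}

#' Continuous toy ensemble
#'
#' A 100-member-style continuum: each member's hinge angle is drawn
#' uniformly over `[0, angle_range]`, plus coordinate jitter. Used with
#' [make_subset_reference] to emulate a reference map built from a random
#' sub-ensemble of a structurally heterogeneous prior.
#'
#' @param n_residues residues in the polymer.
#' @param angle_range upper hinge angle (radians).
#' @param M ensemble size.
#' @param jitter_sd coordinate jitter (Angstrom).
#' @param seed RNG seed.
#' @return An [ensemble_spec] with labels `member_001`...; attribute
#'   `angles` records each member's hinge angle.
#' @export
make_continuous_ensemble <- function(n_residues = 30, angle_range = 1.2,
                                     M = 100, jitter_sd = 0.4, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  angles <- stats::runif(M, 0, angle_range)
  structs <- vector("list", M)
  for (i in seq_len(M)) {
    xyz <- hinged_polymer(n_residues, angles[i]) +
      matrix(stats::rnorm(3 * n_residues, 0, jitter_sd), ncol = 3)
    structs[[i]] <- polymer_structure(xyz, sprintf("member_%03d", i))
  }
  ens <- ensemble_spec(structs)
  attr(ens, "angles") <- angles
  ens
}

## Common grid for an ensemble's model maps: the reference grid is defined
## once from the whole ensemble so member maps and mixtures share it.
ensemble_grid <- function(ensemble, resolution, voxel_size, padding) {
  all_xyz <- do.call(rbind, lapply(ensemble$structures, `[[`, "xyz"))
  lo <- apply(all_xyz, 2, min) - padding
  hi <- apply(all_xyz, 2, max) + padding
  dims <- as.integer(ceiling((hi - lo) / voxel_size)) + 1L
  density_map(array(0, dim = dims), origin = lo, voxel_size = voxel_size)
}

#' Mixture reference map for the two-state benchmark
#'
#' Builds the reference as the population-weighted average of the two
#' state-mean maps (each the equal-weight average over that state's
#' members), normalises it, and injects Gaussian noise at the stated
#' fraction of the clean maximum. The ground truth distributes each state's
#' population uniformly over its members.
#'
#' @param ensemble a two-state ensemble from [make_two_state_ensemble].
#' @param populations length-2 numeric (open, closed), summing to 1.
#' @param resolution map resolution (Angstrom).
#' @param noise_fraction noise sd as a fraction of the clean map maximum.
#' @param seed noise seed.
#' @param voxel_size voxel edge (default `resolution / 3`).
#' @param padding grid margin (default `2 * resolution`).
#' @param model_maps optional pre-computed per-member maps on the common
#'   grid (avoids re-simulation across population sweeps).
#' @return List with `map` (noisy, normalised reference), `truth` (class
#'   `ground_truth`: `weights`, `member_ids`, `clean_map`, `populations`),
#'   `noise` (the [noise_model] used), `model_maps`.
#' @export
make_mixture_reference <- function(ensemble, populations, resolution,
                                   noise_fraction, seed = 1L,
                                   voxel_size = resolution / 3,
                                   padding = 2 * resolution,
                                   model_maps = NULL) {
  states <- ensemble$labels
  st <- unique(states)
  if (length(populations) != length(st))
    stop("population length must match the number of states")
  if (abs(sum(populations) - 1) > 1e-8) stop("populations must sum to 1")
  if (is.null(model_maps)) {
    grid <- ensemble_grid(ensemble, resolution, voxel_size, padding)
    model_maps <- lapply(ensemble$structures, simulate_model_map,
                         grid_of = grid, sigma = 0.225 * resolution)
  }
  M <- length(model_maps)
  w_true <- numeric(M)
  for (k in seq_along(st)) {
    idx <- which(states == st[k])
    w_true[idx] <- populations[k] / length(idx)
  }
  raw <- average_map(model_maps, w_true)
  scale <- max(raw$values)
  clean <- normalize_map(raw)
  nm <- noise_model(noise_fraction, map = clean, seed = seed)
  noisy <- add_noise(clean, nm)
  truth <- structure(list(weights = w_true,
                          member_ids = which(w_true > 0),
                          clean_map = clean, scale = scale,
                          populations = populations,
                          states = st, seed = as.integer(seed)),
                     class = "ground_truth")
  list(map = noisy, truth = truth, noise = nm, model_maps = model_maps)
}

#' Subset reference map (continuous heterogeneity benchmark)
#'
#' Picks a seeded random subset of members, averages their maps with equal
#' weight, normalises and adds noise. Ground truth: uniform weight on the
#' subset, zero elsewhere.
#'
#' @param ensemble an [ensemble_spec].
#' @param subset_size members in the generating subset (default 10).
#' @param resolution map resolution (Angstrom).
#' @param noise_fraction noise sd as fraction of the clean maximum.
#' @param seed seed for both the subset draw and the noise field.
#' @param voxel_size,padding grid parameters as in [make_mixture_reference].
#' @param model_maps optional pre-computed per-member maps.
#' @return List as in [make_mixture_reference]; `truth$member_ids` is the
#'   generating subset.
#' @export
make_subset_reference <- function(ensemble, subset_size = 10, resolution,
                                  noise_fraction, seed = 1L,
                                  voxel_size = resolution / 3,
                                  padding = 2 * resolution,
                                  model_maps = NULL) {
  M <- length(ensemble)
  if (subset_size < 1) stop("subset_size must be >= 1")
  if (subset_size > M) stop("subset_size exceeds the ensemble size")
  if (is.null(model_maps)) {
    grid <- ensemble_grid(ensemble, resolution, voxel_size, padding)
    model_maps <- lapply(ensemble$structures, simulate_model_map,
                         grid_of = grid, sigma = 0.225 * resolution)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  subset <- sort(sample.int(M, subset_size))
  w_true <- numeric(M)
  w_true[subset] <- 1 / subset_size
  raw <- average_map(model_maps, w_true)
  scale <- max(raw$values)
  clean <- normalize_map(raw)
  nm <- noise_model(noise_fraction, map = clean, seed = seed)
  noisy <- add_noise(clean, nm)
  truth <- structure(list(weights = w_true, member_ids = subset,
                          clean_map = clean, scale = scale,
                          seed = as.integer(seed)),
                     class = "ground_truth")
  list(map = noisy, truth = truth, noise = nm, model_maps = model_maps)
}

#' Compositional two-species benchmark
#'
#' Concatenates two ensembles of different molecular composition that share
#' a physical frame, and builds a reference map as the mixture of the two
#' species-mean maps at a stated fraction. Ground truth records the species
#' fraction; labels carry the species tag through reweighting.
#'
#' @param species_a,species_b [ensemble_spec]s aligned to a common frame
#'   (their bounding boxes must overlap).
#' @param mix_fraction fraction of species B in the reference (0..1).
#' @param resolution,noise_fraction,seed,voxel_size,padding as above.
#' @return List with `ensemble` (the concatenation; labels
#'   "A"/"B"), `map`, `truth` (with `species_fraction`), `noise`,
#'   `model_maps`.
#' @export
make_compositional_ensemble <- function(species_a, species_b, mix_fraction,
                                        resolution, noise_fraction,
                                        seed = 1L,
                                        voxel_size = resolution / 3,
                                        padding = 2 * resolution) {
  if (mix_fraction < 0 || mix_fraction > 1)
    stop("mix_fraction must lie in [0, 1]")
  bb <- function(e) {
    xyz <- do.call(rbind, lapply(e$structures, `[[`, "xyz"))
    rbind(apply(xyz, 2, min), apply(xyz, 2, max))
  }
  ba <- bb(species_a); bbx <- bb(species_b)
  if (any(ba[2, ] < bbx[1, ]) || any(bbx[2, ] < ba[1, ]))
    stop("frame mismatch: the two species' bounding boxes are disjoint")
  structs <- c(species_a$structures, species_b$structures)
  labels <- c(rep("A", length(species_a)), rep("B", length(species_b)))
  ## species may differ in atom count; bypass the shared-layout check
  ens <- structure(list(structures = structs, labels = labels),
                   class = "ensemble_spec")
  grid <- ensemble_grid(ens, resolution, voxel_size, padding)
  model_maps <- lapply(structs, simulate_model_map, grid_of = grid,
                       sigma = 0.225 * resolution)
  Ma <- length(species_a); Mb <- length(species_b)
  w_true <- c(rep((1 - mix_fraction) / Ma, Ma), rep(mix_fraction / Mb, Mb))
  raw <- average_map(model_maps, w_true)
  scale <- max(raw$values)
  clean <- normalize_map(raw)
  nm <- noise_model(noise_fraction, map = clean, seed = seed)
  noisy <- add_noise(clean, nm)
  truth <- structure(list(weights = w_true,
                          member_ids = which(w_true > 0),
                          clean_map = clean, scale = scale,
                          species_fraction = mix_fraction,
                          seed = as.integer(seed)),
                     class = "ground_truth")
  list(ensemble = ens, map = noisy, truth = truth, noise = nm,
       model_maps = model_maps)
}

#' Enumerate the two-state benchmark grid
#'
#' The full design crosses 11 open-state populations (0 to 1 in 0.1 steps),
#' three resolutions (3, 6, 10 Angstrom) and two noise levels (1%, 10%): 66
#' maps. The default is a reduced grid for routine runs; set `full = TRUE`
#' for the complete design.
#'
#' @param full enumerate the complete 66-map grid (default FALSE).
#' @param populations,resolutions,noise_fractions overrides for the reduced
#'   grid.
#' @return data.frame with one row per benchmark map (population of the
#'   open state, resolution, noise_fraction).
#' @export
two_state_benchmark_grid <- function(full = FALSE,
                                     populations = c(0.2, 0.5, 0.8),
                                     resolutions = c(6, 10),
                                     noise_fractions = 0.01) {
  if (full) {
    populations <- seq(0, 1, by = 0.1)
    resolutions <- c(3, 6, 10)
    noise_fractions <- c(0.01, 0.10)
  }
  expand.grid(population = populations, resolution = resolutions,
              noise_fraction = noise_fractions)
}

#' Write a benchmark manifest (spec + ground truth + seeds) as JSON
#'
#' @param bench a list returned by one of the reference generators.
#' @param spec named list describing the design (resolution, noise, sizes).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_benchmark_manifest <- function(bench, spec, path) {
  truth <- bench$truth
  jsonlite::write_json(
    list(spec = spec,
         seed = truth$seed,
         noise = list(fraction = bench$noise$fraction, sd = bench$noise$sd,
                      seed = bench$noise$seed),
         ground_truth = list(weights = truth$weights,
                             member_ids = truth$member_ids)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
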