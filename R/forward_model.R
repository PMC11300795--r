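#' Per-element Gaussian kernel table
#'
#' Each atom contributes a single normalised 3D Gaussian to the simulated
#' density. The amplitude (the atom's integrated density, arbitrary map
#' units x A^3) is the zero-angle electron atomic scattering factor obtained
#' from single-Gaussian collapses of the standard five-Gaussian
#' parameterisations for H, C, N, O, P and S; `width` is the corresponding
#' intrinsic real-space width of that fit (A). Model and reference maps use a
#' single shared kernel width, so `width` is informational: the nuisance
#' width sigma (or 0.225 x resolution for reference synthesis) sets the
#' Gaussian spread.
#'
#' Elements absent from the table fall back to an amplitude proportional to
#' atomic number, scaled to the carbon entry.
#'
#' @return data.frame with columns `element`, `amplitude`, `width`.
#' @export
kernel_table <- function() {
  data.frame(
    element   = c("H", "C", "N", "O", "P", "S"),
    amplitude = c(0.5288, 2.5088, 2.2135, 1.9834, 5.7273, 5.1604),
    width     = c(0.81, 0.83, 0.75, 0.69, 0.86, 0.85),
    stringsAsFactors = FALSE
  )
}

## Atomic numbers for the fallback amplitude (proportional to Z, scaled to C).
.atomic_numbers <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7,
                     O = 8, F = 9, Na = 11, Mg = 12, Al = 13, Si = 14,
                     P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Mn = 25,
                     Fe = 26, Co = 27, Ni = 28, Cu = 29, Zn = 30, Se = 34,
                     Br = 35, I = 53)

#' Look up per-atom Gaussian amplitudes
#'
#' @param elements character vector of element symbols.
#' @param table a kernel table, by default [kernel_table()].
#' @return numeric vector of amplitudes.
#' @export
atom_amplitudes <- function(elements, table = kernel_table()) {
  el <- gsub("[0-9 ]", "", elements)
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 10)))
  amp <- table$amplitude[match(el, table$element)]
  miss <- is.na(amp)
  if (any(miss)) {
    z <- .atomic_numbers[el[miss]]
    if (any(is.na(z)))
      stop("unknown element(s): ", paste(unique(el[miss][is.na(z)]), collapse = ", "))
    c_amp <- table$amplitude[table$element == "C"]
    amp[miss] <- c_amp * z / .atomic_numbers[["C"]]
  }
  amp
}

#' Construct an atomic structure
#'
#' A lightweight container for one ensemble member: coordinates plus
#' PDB-style metadata. All structures in an ensemble must share the atom
#' layout (same atom count and order).
#'
#' @param xyz numeric n_atoms x 3 matrix of positions (Angstrom).
#' @param elements character vector of element symbols (length n_atoms).
#' @param atom_names,resid,chain optional per-atom metadata; defaults are
#'   CA-style pseudo-atom records with one atom per residue.
#' @param label provenance tag (ensemble member id, species, source state).
#' @return An object of class `ens_structure`.
#' @export
ens_structure <- function(xyz, elements, atom_names = NULL, resid = NULL,
                          chain = NULL, label = "") {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("'xyz' must have 3 columns")
  if (any(!is.finite(xyz))) stop("coordinates must be finite")
  n <- nrow(xyz)
  if (length(elements) != n) stop("'elements' length must match atom count")
  if (is.null(atom_names)) atom_names <- rep("CA", n)
  if (is.null(resid)) resid <- seq_len(n)
  if (is.null(chain)) chain <- rep("A", n)
  structure(list(xyz = xyz, elements = as.character(elements),
                 atom_names = atom_names, resid = as.integer(resid),
                 chain = as.character(chain), label = as.character(label)),
            class = "ens_structure")
}

#' @export
print.ens_structure <- function(x, ...) {
  cat(sprintf("ens_structure '%s': %d atoms, %d residues\n",
              x$label, nrow(x$xyz), length(unique(paste(x$chain, x$resid)))))
  invisible(x)
}

#' Construct an ensemble
#'
#' @param structures list of [ens_structure] objects sharing an atom layout.
#' @param labels optional member labels; defaults to the structures' own.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(structures, labels = NULL) {
  if (!length(structures)) stop("empty ensemble")
  n <- nrow(structures[[1]]$xyz)
  for (s in structures)
    if (nrow(s$xyz) != n) stop("all ensemble members must share the atom layout")
  if (is.null(labels)) labels <- vapply(structures, `[[`, "", "label")
  if (length(labels) != length(structures)) stop("labels/structures length mismatch")
  structure(list(structures = structures, labels = as.character(labels)),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf("ensemble_spec: M = %d members, %d atoms each\n",
              length(x$structures), nrow(x$structures[[1]]$xyz)))
  invisible(x)
}

#' @export
length.ensemble_spec <- function(x) length(x$structures)

#' Read structures from PDB/mmCIF files
#'
#' Thin wrapper over bio3d's readers. For altloc alternatives the
#' highest-occupancy record is kept; hydrogens are retained if present.
#'
#' @param paths character vector of PDB or mmCIF file paths.
#' @return An [ensemble_spec] (single path: still an ensemble of one).
#' @export
read_structures <- function(paths) {
  structs <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("structure file not found: ", p)
    pdb <- if (grepl("\\.cif$", p, ignore.case = TRUE))
      bio3d::read.cif(p) else bio3d::read.pdb(p)
    a <- pdb$atom
    a$alt[is.na(a$alt)] <- ""
    ## keep highest-occupancy altloc per atom site
    if (any(nzchar(a$alt) & a$alt != " ")) {
      key <- paste(a$chain, a$resno, a$insert, a$elety)
      ord <- order(key, -a$o)
      a <- a[ord, ][!duplicated(key[ord]), ]
      a <- a[order(as.integer(rownames(a))), ]
    }
    elt <- a$elesy
    if (is.null(elt) || all(!nzchar(trimws(elt))))
      elt <- substr(trimws(a$elety), 1, 1)
    ens_structure(cbind(a$x, a$y, a$z), trimws(elt),
                  atom_names = trimws(a$elety), resid = a$resno,
                  chain = a$chain, label = basename(p))
  })
  ensemble_spec(structs)
}

## Stamp normalised per-atom Gaussians onto a voxel grid. Separable 1D
## Gaussian products keep the cost O(atoms x (2*4sigma/voxel)^3); support
## truncated at 4 sigma per axis (mass loss < 0.4%).
stamp_gaussians <- function(xyz, amplitudes, dims, origin, voxel_size, sigma) {
  arr <- array(0, dim = dims)
  cut <- 4 * sigma
  any_inside <- FALSE
  for (a in seq_len(nrow(xyz))) {
    p <- xyz[a, ]
    lo <- pmax(1L, as.integer(ceiling((p - cut - origin) / voxel_size)) + 1L)
    hi <- pmin(dims, as.integer(floor((p + cut - origin) / voxel_size)) + 1L)
    if (any(lo > hi)) next
    any_inside <- TRUE
    gx <- stats::dnorm(origin[1] + (lo[1]:hi[1] - 1) * voxel_size, p[1], sigma)
    gy <- stats::dnorm(origin[2] + (lo[2]:hi[2] - 1) * voxel_size, p[2], sigma)
    gz <- stats::dnorm(origin[3] + (lo[3]:hi[3] - 1) * voxel_size, p[3], sigma)
    arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] +
      amplitudes[a] * (gx %o% gy %o% gz)
  }
  if (!any_inside) stop("structure entirely outside the map grid")
  arr
}

#' Simulate a reference density map from structures
#'
#' Mimics ChimeraX's molmap: each atom contributes a normalised Gaussian of
#' width 0.225 x resolution, amplitudes from the kernel table; for several
#' structures the equal-weight average of the per-structure maps is returned
#' (population-weighted mixtures are built with [average_map]).
#'
#' @param structures an [ensemble_spec], a list of [ens_structure]s, or one
#'   [ens_structure].
#' @param resolution nominal map resolution (Angstrom, > 0).
#' @param voxel_size voxel edge (Angstrom); default `resolution / 3`.
#' @param padding margin around the bounding box (Angstrom); default
#'   `3 * resolution`.
#' @param table kernel table.
#' @return A [density_map].
#' @export
simulate_reference_map <- function(structures, resolution,
                                   voxel_size = resolution / 3,
                                   padding = 3 * resolution,
                                   table = kernel_table()) {
  structures <- as_structure_list(structures)
  if (!length(structures)) stop("no structures supplied")
  if (resolution <= 0) stop("'resolution' must be positive")
  if (voxel_size <= 0) stop("'voxel_size' must be positive")
  all_xyz <- do.call(rbind, lapply(structures, `[[`, "xyz"))
  lo <- apply(all_xyz, 2, min) - padding
  hi <- apply(all_xyz, 2, max) + padding
  dims <- as.integer(ceiling((hi - lo) / voxel_size)) + 1L
  sigma <- 0.225 * resolution
  acc <- array(0, dim = dims)
  for (s in structures) {
    amp <- atom_amplitudes(s$elements, table)
    acc <- acc + stamp_gaussians(s$xyz, amp, dims, lo, voxel_size, sigma)
  }
  density_map(acc / length(structures), origin = lo, voxel_size = voxel_size)
}

as_structure_list <- function(x) {
  if (inherits(x, "ensemble_spec")) x$structures
  else if (inherits(x, "ens_structure")) list(x)
  else x
}

#' Simulate a model density map on an existing grid
#'
#' Builds the per-structure density entering the likelihood: the same grid
#' (origin, voxel size, shape) as the reference map, one shared Gaussian
#' kernel width `sigma` (the nuisance parameter) for every atom, amplitudes
#' from the kernel table.
#'
#' @param structure an [ens_structure].
#' @param grid_of the [density_map] whose grid is reused.
#' @param sigma kernel width (Angstrom, > 0).
#' @param table kernel table.
#' @return A [density_map] on the same grid as `grid_of`.
#' @export
simulate_model_map <- function(structure, grid_of, sigma,
                               table = kernel_table()) {
  stopifnot(inherits(structure, "ens_structure"), inherits(grid_of, "density_map"))
  if (sigma <= 0) stop("'sigma' must be positive")
  if (nrow(structure$xyz) == 0) stop("structure has no atoms")
  amp <- atom_amplitudes(structure$elements, table)
  arr <- stamp_gaussians(structure$xyz, amp, dim(grid_of$values),
                         grid_of$origin, grid_of$voxel_size, sigma)
  density_map(arr, origin = grid_of$origin, voxel_size = grid_of$voxel_size)
}

#' Weighted average of density maps
#'
#' Voxel-wise weighted sum; with normalised weights this is the posterior
#' (or prior) ensemble-average map.
#'
#' @param models list of [density_map]s on a shared grid.
#' @param weights numeric weights, one per map.
#' @return A [density_map].
#' @export
average_map <- function(models, weights) {
  if (length(models) != length(weights))
    stop("weights/models length mismatch")
  for (m in models[-1])
    if (!same_grid(models[[1]], m)) stop("grid mismatch among model maps")
  acc <- array(0, dim = dim(models[[1]]$values))
  for (i in seq_along(models)) acc <- acc + weights[i] * models[[i]]$values
  density_map(acc, origin = models[[1]]$origin,
              voxel_size = models[[1]]$voxel_size)
}

## Small rotation set for the coarse rigid fit: identity plus rotations about
## the x, y, z axes through the structure centroid.
.rotation_set <- function(angles) {
  rots <- list(diag(3))
  for (ax in 1:3) for (th in angles) {
    c_ <- cos(th); s_ <- sin(th)
    R <- diag(3)
    idx <- setdiff(1:3, ax)
    R[idx[1], idx[1]] <- c_; R[idx[2], idx[2]] <- c_
    R[idx[1], idx[2]] <- -s_; R[idx[2], idx[1]] <- s_
    rots[[length(rots) + 1L]] <- R
  }
  rots
}

#' Coarse rigid-body fit of a structure into a map
#'
#' Convenience exhaustive search over a small translation grid and rotation
#' set, maximising the correlation between the reference map and the
#' structure's simulated map. Intended for roughly pre-positioned structures;
#' it is not a replacement for a full 6D fitting tool. Deterministic: ties
#' keep the earliest (lowest-index) transform, so an already-optimal
#' structure comes back unchanged.
#'
#' @param structure an [ens_structure], near the map region.
#' @param ref reference [density_map].
#' @param resolution map resolution (Angstrom); the simulated map uses
#'   sigma = 0.225 x resolution.
#' @param max_shift translation search half-range (Angstrom).
#' @param shift_step translation step (Angstrom); default one voxel.
#' @param rot_angles rotation angles (radians) applied about each axis.
#' @return The transformed [ens_structure] (input never mutated).
#' @export
grid_rigid_fit <- function(structure, ref, resolution,
                           max_shift = 2 * ref$voxel_size,
                           shift_step = ref$voxel_size,
                           rot_angles = c(-0.1, 0.1)) {
  sigma <- 0.225 * resolution
  shifts <- seq(-max_shift, max_shift, by = shift_step)
  rots <- .rotation_set(rot_angles)
  ctr <- colMeans(structure$xyz)
  best <- -Inf; best_xyz <- structure$xyz
  for (R in rots) {
    xyz_r <- sweep(sweep(structure$xyz, 2, ctr) %*% t(R), 2, ctr, `+`)
    for (dx in shifts) for (dy in shifts) for (dz in shifts) {
      xyz_t <- sweep(xyz_r, 2, c(dx, dy, dz), `+`)
      cand <- structure; cand$xyz <- xyz_t
      m <- tryCatch(simulate_model_map(cand, ref, sigma), error = function(e) NULL)
      if (is.null(m)) next
      cc <- suppressWarnings(stats::cor(as.vector(ref$values), as.vector(m$values)))
      if (is.finite(cc) && cc > best + 1e-12) {
        best <- cc; best_xyz <- xyz_t
      }
    }
  }
  out <- structure
  out$xyz <- best_xyz
  out
}

#' Write a structure as PDB
#'
#' Minimal single-model PDB writer for ensemble members (via bio3d).
#'
#' @param structure an [ens_structure].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "ens_structure"))
  n <- nrow(structure$xyz)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(structure$xyz)),
                   type = rep("ATOM", n),
                   resno = structure$resid,
                   resid = rep("ALA", n),
                   eleno = seq_len(n),
                   elety = structure$atom_names,
                   chain = structure$chain,
                   elesy = structure$elements)
  invisible(path)
}
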