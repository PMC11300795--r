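#' Construct a density map
#'
#' A `density_map` is a 3D voxel grid of density values together with the
#' physical position of its first voxel (`origin`, in Angstrom) and an
#' isotropic voxel edge length (`voxel_size`, Angstrom). The array is stored
#' in logical (x, y, z) order: `values[i, j, k]` is the density at physical
#' position `origin + (i - 1, j - 1, k - 1) * voxel_size`.
#'
#' @param values numeric 3D array of densities.
#' @param origin numeric length-3, physical coordinates (Angstrom) of voxel
#'   (1, 1, 1).
#' @param voxel_size positive scalar, voxel edge length in Angstrom.
#' @return An object of class `density_map`.
#' @export
density_map <- function(values, origin = c(0, 0, 0), voxel_size = 1) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (length(origin) != 3L || !is.numeric(origin) || any(!is.finite(origin)))
    stop("'origin' must be a finite numeric vector of length 3")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("'voxel_size' must be a positive scalar")
  if (any(dim(values) < 1L)) stop("all map dimensions must be >= 1")
  storage.mode(values) <- "double"
  structure(list(values = values,
                 origin = as.numeric(origin),
                 voxel_size = as.numeric(voxel_size)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density_map: %d x %d x %d voxels, %.3f A/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  origin (A): %.3f %.3f %.3f\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  density range: [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.density_map <- function(x) dim(x$values)

## Physical coordinates of the voxel centres along each axis.
grid_axes <- function(map) {
  d <- dim(map$values)
  lapply(1:3, function(a) map$origin[a] + (seq_len(d[a]) - 1) * map$voxel_size)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$origin - b$origin) < tol) &&
    abs(a$voxel_size - b$voxel_size) < tol
}

## Flat voxel ids: the external contract is 0-based C-order (last axis
## fastest) over the (x, y, z) array; R's native linear index is 1-based
## Fortran order. Both converters are exercised in the tests.
r_index_to_flat <- function(idx, d) {
  k <- (idx - 1L) %/% (d[1] * d[2])
  rem <- (idx - 1L) %% (d[1] * d[2])
  j <- rem %/% d[1]
  i <- rem %% d[1]
  i * (d[2] * d[3]) + j * d[3] + k
}

flat_to_r_index <- function(flat, d) {
  i <- flat %/% (d[2] * d[3])
  rem <- flat %% (d[2] * d[3])
  j <- rem %/% d[3]
  k <- rem %% d[3]
  i + j * d[1] + k * d[1] * d[2] + 1L
}

#' Read an MRC/CCP4 density map
#'
#' Reads a mode-2 (float32) MRC volume, resolving the MAPC/MAPR/MAPS axis
#' permutation so the returned array is in logical (x, y, z) order. The origin
#' is taken from the ORIGIN header words when set, otherwise from
#' NXSTART/NYSTART/NZSTART times the voxel size. Anisotropic voxels are
#' rejected (resampling is out of scope).
#'
#' @param path path to an MRC/CCP4 file.
#' @return A [density_map].
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr_raw <- readBin(con, "raw", n = 1024L)
  if (length(hdr_raw) < 1024L) stop("malformed header: file shorter than 1024 bytes")
  ih <- readBin(hdr_raw, "integer", n = 56L, size = 4L, endian = "little")
  fh <- readBin(hdr_raw, "double", n = 56L, size = 4L, endian = "little")
  nc <- ih[1]; nr <- ih[2]; ns <- ih[3]; mode <- ih[4]
  if (any(c(nc, nr, ns) < 1) || any(c(nc, nr, ns) > 1e5))
    stop("malformed header: implausible dimensions")
  if (mode != 2L) stop("unsupported MRC mode ", mode, " (field MODE; only mode 2 float32 is read)")
  nstart <- ih[5:7]
  m_grid <- ih[8:10]
  cella <- fh[11:13]
  mapcrs <- ih[17:19]
  if (!all(sort(mapcrs) == 1:3))
    stop("malformed header: MAPC/MAPR/MAPS must be a permutation of 1,2,3")
  nsymbt <- ih[24]
  if (nsymbt < 0) stop("malformed header: negative NSYMBT")
  org <- fh[50:52]
  if (any(m_grid <= 0)) stop("malformed header: non-positive MX/MY/MZ")
  vox <- cella / m_grid
  if (any(vox <= 0)) stop("malformed header: non-positive cell dimensions (field CELLA)")
  if (max(vox) - min(vox) > 1e-4 * max(vox))
    stop("anisotropic voxels (field CELLA/MX..MZ): voxel sizes ",
         paste(signif(vox, 6), collapse = " "), " A; resampling not supported")
  if (nsymbt > 0) invisible(readBin(con, "raw", n = nsymbt))
  nvox <- as.numeric(nc) * nr * ns
  vals <- readBin(con, "double", n = nvox, size = 4L, endian = "little")
  if (length(vals) < nvox) stop("malformed header: data block truncated")
  arr <- array(vals, dim = c(nc, nr, ns))
  ## arr axes are (column, row, section) = crystallographic axes mapcrs;
  ## permute so axis a of the result is the logical axis a (x, y, z).
  perm <- match(1:3, mapcrs)
  arr <- aperm(arr, perm)
  ## Per-axis start offsets follow the same permutation as the data axes.
  nstart_xyz <- nstart[perm]
  origin <- if (any(org != 0)) org else nstart_xyz * vox[1]
  density_map(arr, origin = origin, voxel_size = vox[1])
}

#' Write a density map as MRC
#'
#' Writes mode-2 float32 with MAPC/MAPR/MAPS = 1,2,3 and the physical origin
#' in the ORIGIN header words.
#'
#' @param map a [density_map].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(d)                       # NX NY NZ
  wi(2L)                      # MODE
  wi(c(0L, 0L, 0L))           # NXSTART..
  wi(d)                       # MX MY MZ
  wf(d * map$voxel_size)      # CELLA
  wf(c(90, 90, 90))           # CELLB
  wi(1:3)                     # MAPC MAPR MAPS
  v <- map$values
  wf(c(min(v), max(v), mean(v)))  # DMIN DMAX DMEAN
  wi(c(1L, 0L))               # ISPG, NSYMBT
  wi(integer(25L))            # EXTRA (words 25..49)
  wf(map$origin)              # ORIGIN (words 50-52)
  writeBin(charToRaw("MAP "), con)                    # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)    # MACHST little-endian
  wf(stats::sd(v))            # RMS
  wi(0L)                      # NLABL
  writeBin(raw(800L), con)    # labels
  writeBin(as.numeric(v), con, size = 4L, endian = "little")
  invisible(path)
}

#' Normalise a density map
#'
#' Zeroes negative voxels and rescales so the maximum density is 1, the
#' processing applied to every map (reference and model) before voxel
#' selection. Idempotent.
#'
#' @param map a [density_map].
#' @return The normalised [density_map].
#' @export
normalize_map <- function(map) {
  stopifnot(inherits(map, "density_map"))
  v <- map$values
  v[v < 0] <- 0
  m <- max(v)
  if (m <= 0) stop("cannot normalise: all map values are <= 0")
  map$values <- v / m
  map
}

#' Describe a Gaussian noise model for a map
#'
#' The noise standard deviation is a stated fraction of the clean map's
#' maximum density (1% or 10% in the benchmark designs).
#'
#' @param fraction noise level as a fraction of the map maximum (>= 0).
#' @param map the clean map the fraction refers to (used to compute `sd`);
#'   may be omitted if `sd` is given directly.
#' @param sd noise standard deviation in map units; computed from
#'   `fraction * max(map$values)` when omitted.
#' @param seed integer RNG seed recorded with the model.
#' @return An object of class `noise_model` with fields `fraction`, `sd`,
#'   `seed`.
#' @export
noise_model <- function(fraction, map = NULL, sd = NULL, seed = 1L) {
  if (fraction < 0) stop("noise fraction must be >= 0")
  if (is.null(sd)) {
    if (is.null(map)) stop("either 'map' or 'sd' must be supplied")
    sd <- fraction * max(map$values)
  }
  structure(list(fraction = fraction, sd = sd, seed = as.integer(seed)),
            class = "noise_model")
}

#' Add iid Gaussian noise to a map
#'
#' @param map a [density_map] (the clean map).
#' @param model a [noise_model]; its `sd` is the noise standard deviation and
#'   its `seed` makes the field reproducible.
#' @return The noisy [density_map].
#' @export
add_noise <- function(map, model) {
  stopifnot(inherits(map, "density_map"), inherits(model, "noise_model"))
  if (model$sd == 0) return(map)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(model$seed)
  map$values <- map$values + array(stats::rnorm(length(map$values), 0, model$sd),
                                   dim = dim(map$values))
  map
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Select the voxels entering the reweighting dataset
#'
#' A voxel is selected if its reference density exceeds the reference
#' threshold (3 x sigma_noise, or a user-supplied absolute threshold), or if
#' any model map exceeds its own threshold of 3 x the standard deviation of
#' that model map. The selection is the union of the two sources, so voxels
#' where models predict density the reference lacks stay in the dataset and
#' are penalised by the likelihood.
#'
#' @param ref reference [density_map].
#' @param models list of model [density_map]s on the same grid.
#' @param noise a [noise_model] for the reference map (used for the
#'   3 x sigma_noise threshold), or `NULL` when `ref_threshold` is given.
#' @param ref_threshold optional absolute reference-density threshold
#'   overriding `3 * noise$sd` (as used for experimental maps with an
#'   author-suggested contour level).
#' @param sigma_kernel the kernel width (Angstrom) used to build the model
#'   maps, recorded in the selection.
#' @return An object of class `voxel_selection` with fields `indices`
#'   (0-based C-order flat voxel ids, ascending), `r_indices` (the same
#'   voxels as 1-based R linear indices), `ref_density` (length N),
#'   `model_density` (N x M matrix), `sigma_kernel`, `n_voxels`, `n_models`,
#'   `model_sds`.
#' @export
select_voxels <- function(ref, models, noise = NULL, ref_threshold = NULL,
                          sigma_kernel = NA_real_) {
  stopifnot(inherits(ref, "density_map"))
  if (!length(models)) stop("at least one model map is required")
  for (m in models)
    if (!same_grid(ref, m))
      stop("grid mismatch between reference and model maps (origin/voxel_size/shape must agree)")
  if (is.null(ref_threshold)) {
    if (is.null(noise)) stop("supply either a noise_model or an absolute ref_threshold")
    ref_threshold <- 3 * noise$sd
  }
  d <- dim(ref$values)
  keep <- as.vector(ref$values) > ref_threshold
  model_sds <- vapply(models, function(m) stats::sd(as.vector(m$values)), 0)
  for (i in seq_along(models))
    keep <- keep | (as.vector(models[[i]]$values) > 3 * model_sds[i])
  r_idx <- which(keep)
  if (!length(r_idx))
    stop("empty voxel selection: no voxel exceeds the thresholds; review the ",
         "reference threshold (", signif(ref_threshold, 4), ") and model thresholds")
  flat <- r_index_to_flat(r_idx, d)
  ord <- order(flat)
  flat <- flat[ord]; r_idx <- r_idx[ord]
  md <- vapply(models, function(m) as.vector(m$values)[r_idx],
               numeric(length(r_idx)))
  md <- matrix(md, nrow = length(r_idx))
  md[md < 0] <- 0
  rd <- as.vector(ref$values)[r_idx]
  rd[rd < 0] <- 0
  structure(list(indices = flat,
                 r_indices = r_idx,
                 ref_density = rd,
                 model_density = md,
                 sigma_kernel = sigma_kernel,
                 n_voxels = length(r_idx),
                 n_models = length(models),
                 model_sds = model_sds),
            class = "voxel_selection")
}

#' @export
print.voxel_selection <- function(x, ...) {
  cat(sprintf("voxel_selection: N = %d voxels, M = %d models (kernel sigma %.3g A)\n",
              x$n_voxels, x$n_models, x$sigma_kernel))
  invisible(x)
}

## Restrict a selection to a subset of the model columns, re-deriving the
## union of above-threshold voxels for the kept models. Requires the full
## maps, because dropped models may have been the only reason a voxel was in.
reselect_voxels <- function(ref, models, keep, noise = NULL,
                            ref_threshold = NULL, sigma_kernel = NA_real_) {
  select_voxels(ref, models[keep], noise = noise, ref_threshold = ref_threshold,
                sigma_kernel = sigma_kernel)
}

#' Estimate the likelihood noise variance from the solvent region
#'
#' The Gaussian-likelihood variance (the experimental-error term) is
#' approximated by the variance of the reference density over voxels outside
#' the molecular envelope: voxels where every model map is below its
#' 3 x sigma_map threshold. A floor of `1e-6 * max(ref)^2` guards noiseless
#' synthetic maps against a zero variance.
#'
#' @param ref reference [density_map].
#' @param models list of model [density_map]s on the same grid.
#' @return Scalar noise variance (map units squared).
#' @export
estimate_sigma_L <- function(ref, models) {
  stopifnot(inherits(ref, "density_map"))
  for (m in models)
    if (!same_grid(ref, m)) stop("grid mismatch between reference and model maps")
  outside <- rep(TRUE, length(ref$values))
  for (m in models) {
    thr <- 3 * stats::sd(as.vector(m$values))
    outside <- outside & (as.vector(m$values) <= thr)
  }
  n_out <- sum(outside)
  if (n_out < 2)
    stop("no voxels outside the molecular region; cannot estimate the noise variance")
  s2 <- stats::var(as.vector(ref$values)[outside])
  max(s2, 1e-6 * max(ref$values)^2)
}

#' Export a voxel selection as TSV
#'
#' Columns: flat index (0-based C-order), x/y/z voxel indices (0-based), and
#' the reference density.
#'
#' @param sel a `voxel_selection`.
#' @param map the [density_map] the selection refers to (for the grid shape).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_selection_tsv <- function(sel, map, path) {
  d <- dim(map$values)
  flat <- sel$indices
  i <- flat %/% (d[2] * d[3])
  rem <- flat %% (d[2] * d[3])
  j <- rem %/% d[3]
  k <- rem %% d[3]
  utils::write.table(
    data.frame(index = flat, x = i, y = j, z = k, ref_density = sel$ref_density),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
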