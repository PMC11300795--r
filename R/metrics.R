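#' Map correlation coefficient
#'
#' Correlation between two maps over a voxel set. `method = "pearson"`
#' (default) is the correlation about the means; `method = "overlap"` is the
#' about-zero overlap `sum(ab) / sqrt(sum(a^2) sum(b^2))`.
#'
#' @param a,b [density_map]s on the same grid.
#' @param voxels optional integer vector of 1-based R linear voxel indices
#'   (e.g. `selection$r_indices`); default all voxels.
#' @param method "pearson" or "overlap".
#' @return Correlation in [-1, 1].
#' @export
map_cc <- function(a, b, voxels = NULL, method = c("pearson", "overlap")) {
  method <- match.arg(method)
  if (!same_grid(a, b)) stop("grid mismatch between maps")
  va <- as.vector(a$values); vb <- as.vector(b$values)
  if (!is.null(voxels)) { va <- va[voxels]; vb <- vb[voxels] }
  if (length(va) < 2) stop("need at least 2 voxels")
  if (method == "pearson") {
    if (stats::sd(va) == 0 || stats::sd(vb) == 0)
      stop("zero variance on one of the density vectors")
    stats::cor(va, vb)
  } else {
    den <- sqrt(sum(va^2) * sum(vb^2))
    if (den == 0) stop("zero norm on one of the density vectors")
    sum(va * vb) / den
  }
}

#' Per-residue Manders overlap (SMOC-style local fit score)
#'
#' For each residue, the voxels within `radius` of any of its atoms form the
#' residue zone; the score is the Manders overlap coefficient
#' `sum(ref * sim) / sqrt(sum(ref^2) sum(sim^2))` between the reference map
#' and the structure's simulated density over that zone. An empty zone (or a
#' zone where either map is identically zero) scores 0 with a warning.
#'
#' @param ref reference [density_map], aligned with the structure.
#' @param structure an [ens_structure].
#' @param sigma simulation kernel width (Angstrom).
#' @param radius zone radius around each atom (Angstrom, default 5).
#' @return data.frame (class `residue_score_track`) with columns `chain`,
#'   `resid`, `score`; metric name in attribute `metric`.
#' @export
smoc <- function(ref, structure, sigma, radius = 5) {
  stopifnot(inherits(ref, "density_map"), inherits(structure, "ens_structure"))
  if (nrow(structure$xyz) == 0) stop("structure has no atoms")
  sim <- simulate_model_map(structure, ref, sigma)
  d <- dim(ref$values)
  rv <- ref$values; sv <- sim$values
  key <- paste(structure$chain, structure$resid)
  res_keys <- unique(key)
  out <- data.frame(chain = character(0), resid = integer(0), score = numeric(0))
  warned <- FALSE
  for (rk in res_keys) {
    idx_atoms <- which(key == rk)
    zone <- logical(0)
    vox <- integer(0)
    for (a in idx_atoms) {
      p <- structure$xyz[a, ]
      lo <- pmax(1L, as.integer(ceiling((p - radius - ref$origin) / ref$voxel_size)) + 1L)
      hi <- pmin(d, as.integer(floor((p + radius - ref$origin) / ref$voxel_size)) + 1L)
      if (any(lo > hi)) next
      gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
      cx <- ref$origin[1] + (gx - 1) * ref$voxel_size
      cy <- ref$origin[2] + (gy - 1) * ref$voxel_size
      cz <- ref$origin[3] + (gz - 1) * ref$voxel_size
      dist2 <- outer(outer((cx - p[1])^2, (cy - p[2])^2, `+`), (cz - p[3])^2, `+`)
      sub <- which(dist2 <= radius^2, arr.ind = TRUE)
      if (nrow(sub)) {
        vox <- c(vox, (gx[sub[, 1]]) + (gy[sub[, 2]] - 1L) * d[1] +
                   (gz[sub[, 3]] - 1L) * d[1] * d[2])
      }
    }
    vox <- unique(vox)
    if (!length(vox)) {
      score <- 0; warned <- TRUE
    } else {
      r <- rv[vox]; s <- sv[vox]
      den <- sum(r^2) * sum(s^2)
      score <- if (den <= 0) { warned <- TRUE; 0 } else sum(r * s) / sqrt(den)
    }
    out <- rbind(out, data.frame(chain = structure$chain[idx_atoms[1]],
                                 resid = structure$resid[idx_atoms[1]],
                                 score = score))
  }
  if (warned) warning("some residue zones were empty or had zero density; scored 0")
  attr(out, "metric") <- "SMOC"
  class(out) <- c("residue_score_track", class(out))
  out
}

#' Jensen-Shannon divergence between discrete distributions
#'
#' `JS(p, q) = KL(p||m)/2 + KL(q||m)/2` with `m = (p + q)/2`, natural
#' logarithm. Symmetric, bounded by ln 2.
#'
#' @param p,q non-negative vectors on the same support, each summing to 1.
#' @return Divergence in [0, ln 2].
#' @export
jensen_shannon <- function(p, q) {
  if (length(p) != length(q)) stop("distributions must share their support length")
  if (any(p < 0) || any(q < 0)) stop("negative probability mass")
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8)
    stop("distributions must be normalised")
  m <- (p + q) / 2
  kl_part <- function(a) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / m[nz]))
  }
  (kl_part(p) + kl_part(q)) / 2
}

#' Jensen-Shannon divergence between two weighted ensembles
#'
#' Compares two ensembles through weighted histograms of a scalar structural
#' feature (default: heavy-atom RMSD to a fixed reference structure, after
#' superposition). Bin edges default to Freedman-Diaconis on the pooled
#' feature values, shared by both histograms.
#'
#' @param ens_a,ens_b [ensemble_spec]s with a common atom layout.
#' @param weights_a,weights_b normalised member weights (default uniform).
#' @param reference reference [ens_structure] for the RMSD feature; default
#'   the first member of `ens_a`.
#' @param feature optional function(structure) -> scalar overriding the RMSD
#'   feature.
#' @param breaks optional numeric vector of bin edges.
#' @return Divergence in [0, ln 2].
#' @export
ensemble_js_divergence <- function(ens_a, ens_b, weights_a = NULL,
                                   weights_b = NULL, reference = NULL,
                                   feature = NULL, breaks = NULL) {
  if (is.null(weights_a)) weights_a <- rep(1 / length(ens_a), length(ens_a))
  if (is.null(weights_b)) weights_b <- rep(1 / length(ens_b), length(ens_b))
  if (is.null(feature)) {
    if (is.null(reference)) reference <- ens_a$structures[[1]]
    feature <- function(s) structure_rmsd(s, reference)
  }
  fa <- vapply(ens_a$structures, feature, 0)
  fb <- vapply(ens_b$structures, feature, 0)
  if (is.null(breaks)) {
    pooled <- c(fa, fb)
    h <- 2 * stats::IQR(pooled) / length(pooled)^(1 / 3)   # Freedman-Diaconis
    if (h <= 0) h <- max(diff(range(pooled)), 1e-8) / 10
    lo <- min(pooled) - h / 2
    n_bins <- max(1L, ceiling((max(pooled) - lo) / h))
    breaks <- lo + (0:n_bins) * h
  }
  if (length(breaks) < 2) stop("need at least 2 bin edges")
  bin <- function(f, w) {
    idx <- findInterval(f, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    p <- numeric(length(breaks) - 1)
    for (i in seq_along(idx)) p[idx[i]] <- p[idx[i]] + w[i]
    p / sum(p)
  }
  jensen_shannon(bin(fa, weights_a), bin(fb, weights_b))
}

#' RMSD between two structures after superposition
#'
#' Heavy-atom (all-atom) RMSD after least-squares superposition, via bio3d.
#'
#' @param a,b [ens_structure]s with the same atom count.
#' @param fit superpose before computing (default TRUE).
#' @return RMSD in Angstrom.
#' @export
structure_rmsd <- function(a, b, fit = TRUE) {
  if (nrow(a$xyz) != nrow(b$xyz)) stop("atom-count mismatch")
  xa <- as.vector(t(a$xyz)); xb <- as.vector(t(b$xyz))
  inds <- seq_along(xa)
  as.numeric(bio3d::rmsd(xa, xb, a.inds = inds, b.inds = inds, fit = fit))
}

## Representative atom per residue: the alpha-carbon when present, else the
## geometric centre of the residue's atoms. Returns K x 3 matrix and keys.
representative_coords <- function(s) {
  key <- paste(s$chain, s$resid)
  res_keys <- unique(key)
  out <- matrix(0, nrow = length(res_keys), ncol = 3)
  for (i in seq_along(res_keys)) {
    idx <- which(key == res_keys[i])
    ca <- idx[s$atom_names[idx] == "CA"]
    out[i, ] <- if (length(ca)) s$xyz[ca[1], ] else colMeans(s$xyz[idx, , drop = FALSE])
  }
  list(xyz = out, keys = res_keys)
}

## Superpose all members' representative coordinates onto the weighted mean
## conformation (two iterations of weighted-mean refitting).
superposed_rep_coords <- function(ensemble, weights, passes = 2, fit = TRUE) {
  reps <- lapply(ensemble$structures, representative_coords)
  keys <- reps[[1]]$keys
  coords <- lapply(reps, `[[`, "xyz")
  mean_xyz <- coords[[1]]
  if (!fit) {
    mean_xyz <- Reduce(`+`, Map(function(x, w) w * x, coords, as.list(weights)))
    return(list(coords = coords, mean = mean_xyz, keys = keys))
  }
  for (pass in seq_len(passes)) {
    inds <- seq_len(3 * nrow(mean_xyz))
    fitted <- lapply(coords, function(x) {
      xv <- bio3d::fit.xyz(fixed = as.vector(t(mean_xyz)),
                           mobile = as.vector(t(x)),
                           fixed.inds = inds, mobile.inds = inds)
      matrix(xv, ncol = 3, byrow = TRUE)
    })
    mean_xyz <- Reduce(`+`, Map(function(x, w) w * x, fitted, as.list(weights)))
    coords <- fitted
  }
  list(coords = coords, mean = mean_xyz, keys = keys)
}

#' Weighted per-residue RMSF
#'
#' Root-mean-square fluctuation of each residue's representative atom about
#' the weighted mean conformation, `sqrt(sum_i w_i |x_i - xbar|^2)`, after
#' iterated weighted-mean superposition. With uniform weights this is the
#' textbook ensemble RMSF.
#'
#' @param ensemble an [ensemble_spec].
#' @param weights normalised member weights (default uniform).
#' @param fit superpose members onto the weighted mean first (default TRUE;
#'   set FALSE for ensembles already in a common frame).
#' @return data.frame with `chain`, `resid` keys (as `residue`) and `rmsf`
#'   (Angstrom).
#' @export
weighted_rmsf <- function(ensemble, weights = NULL, fit = TRUE) {
  M <- length(ensemble)
  if (is.null(weights)) weights <- rep(1 / M, M)
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must be normalised")
  sp <- superposed_rep_coords(ensemble, weights, fit = fit)
  K <- nrow(sp$mean)
  rmsf <- sqrt(Reduce(`+`, Map(function(x, w) {
    w * rowSums((x - sp$mean)^2)
  }, sp$coords, as.list(weights))))
  data.frame(residue = sp$keys, rmsf = rmsf)
}

#' Weighted PCA of ensemble coordinates
#'
#' Eigendecomposition of the weighted covariance of the superposed
#' representative-atom coordinates. Components are ordered by variance;
#' each eigenvector's sign is fixed so its largest-magnitude entry is
#' positive. Variance fractions are relative to the total coordinate
#' variance (the covariance trace), so the reported fractions sum to at
#' most 1.
#'
#' @param ensemble an [ensemble_spec].
#' @param weights normalised member weights (default uniform).
#' @param n_components number of components to return (default 3).
#' @param fit superpose members onto the weighted mean first (default TRUE).
#' @return List with `vectors` (3K x n_components), `variance` (eigenvalues,
#'   A^2), `fraction` (of total variance), `mean` (3K), `weights`.
#' @export
weighted_pca <- function(ensemble, weights = NULL, n_components = 3, fit = TRUE) {
  M <- length(ensemble)
  if (is.null(weights)) weights <- rep(1 / M, M)
  sp <- superposed_rep_coords(ensemble, weights, fit = fit)
  X <- t(vapply(sp$coords, function(x) as.vector(t(x)),
                numeric(3 * nrow(sp$mean))))
  if (n_components > ncol(X)) stop("n_components exceeds 3 x residue count")
  mu <- as.vector(crossprod(X, weights))
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc * sqrt(weights))   # sum_i w_i (x_i - mu)(x_i - mu)^T
  eig <- eigen(C, symmetric = TRUE)
  total <- sum(diag(C))
  nc <- n_components
  V <- eig$vectors[, seq_len(nc), drop = FALSE]
  for (j in seq_len(nc)) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  lam <- pmax(eig$values[seq_len(nc)], 0)
  list(vectors = V, variance = lam,
       fraction = if (total > 0) lam / total else rep(0, nc),
       mean = mu, weights = weights)
}

#' Export principal modes as pseudo-trajectory PDB frames
#'
#' Writes, for each requested mode, frames interpolating the mean structure
#' along +/- 2 standard deviations of the mode (representative atoms as CA
#' pseudo-atoms).
#'
#' @param pca result of [weighted_pca].
#' @param keys residue keys (chain/resid) for naming; optional.
#' @param path output PDB path.
#' @param mode which component (default 1).
#' @param n_frames frames along the mode (default 5).
#' @return `path`, invisibly.
#' @export
write_mode_pdb <- function(pca, path, keys = NULL, mode = 1, n_frames = 5) {
  sdv <- sqrt(pca$variance[mode])
  amps <- seq(-2 * sdv, 2 * sdv, length.out = n_frames)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  K <- length(pca$mean) / 3
  for (f in seq_along(amps)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- matrix(pca$mean + amps[f] * pca$vectors[, mode], ncol = 3,
                  byrow = TRUE)
    for (i in seq_len(K)) {
      writeLines(sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, i, xyz[i, 1], xyz[i, 2], xyz[i, 3]), con)
    }
    writeLines("ENDMDL", con)
  }
  invisible(path)
}
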