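test_that("map correlation reproduces the textbook Pearson formula", {
  a <- density_map(array(c(1, 2, 3, 4, 5, 6), dim = c(1, 2, 3)))
  expect_equal(map_cc(a, a), 1)
  b <- a; b$values <- -a$values + 10
  expect_equal(map_cc(a, b), -1)
  set.seed(1)
  c6 <- a; c6$values <- array(runif(6), dim = dim(a$values))
  va <- as.vector(a$values); vc <- as.vector(c6$values)
  hand <- sum((va - mean(va)) * (vc - mean(vc))) /
    sqrt(sum((va - mean(va))^2) * sum((vc - mean(vc))^2))
  expect_equal(map_cc(a, c6), hand)
  ## restriction to a voxel subset
  expect_equal(map_cc(a, c6, voxels = 2:5),
               cor(va[2:5], vc[2:5]))
  flat <- a; flat$values <- array(1, dim = dim(a$values))
  expect_error(map_cc(a, flat), "zero variance")
  ## overlap variant is about zero, not about the mean
  expect_equal(map_cc(a, c6, method = "overlap"),
               sum(va * vc) / sqrt(sum(va^2) * sum(vc^2)))
})

test_that("SMOC scores self-overlap as 1 and disjoint support as 0", {
  s <- ens_structure(rbind(c(0, 0, 0), c(6, 0, 0)), elements = c("C", "C"),
                     resid = c(1, 2))
  grid <- density_map(array(0, dim = c(13, 9, 9)), origin = c(-4, -4, -4),
                      voxel_size = 1)
  sim <- simulate_model_map(s, grid, sigma = 1.2)
  sm <- smoc(sim, s, sigma = 1.2, radius = 4)
  expect_equal(nrow(sm), 2)
  expect_true(all(abs(sm$score - 1) < 1e-6))
  ## reference with no density in the zones scores 0
  far <- density_map(array(0, dim = dim(grid$values)), origin = grid$origin,
                     voxel_size = 1)
  far$values[13, 9, 9] <- 1
  expect_warning(sm0 <- smoc(far, s, sigma = 1.2, radius = 2), "zero density")
  expect_true(all(sm0$score == 0))
})

test_that("SMOC matches a hand-computed Manders overlap on a toy zone", {
  s <- ens_structure(matrix(c(0, 0, 0), ncol = 3), elements = "C")
  grid <- density_map(array(0, dim = c(7, 7, 7)), origin = c(-3, -3, -3),
                      voxel_size = 1)
  set.seed(8)
  ref <- grid; ref$values <- array(runif(343), dim = c(7, 7, 7))
  sm <- smoc(ref, s, sigma = 1, radius = 2.5)
  ## oracle: enumerate all voxels within 2.5 A of the atom, apply the formula
  sim <- simulate_model_map(s, grid, sigma = 1)
  ax <- -3:3
  keep <- which(outer(outer(ax^2, ax^2, `+`), ax^2, `+`) <= 2.5^2)
  r <- as.vector(ref$values)[keep]; m <- as.vector(sim$values)[keep]
  expect_equal(sm$score, sum(r * m) / sqrt(sum(r^2) * sum(m^2)))
})

test_that("Jensen-Shannon divergence has exact closed forms", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(jensen_shannon(p, p), 0, tolerance = 1e-12)
  expect_equal(jensen_shannon(c(1, 0), c(0, 1)), log(2), tolerance = 1e-12)
  set.seed(3)
  a <- runif(8); a <- a / sum(a)
  b <- runif(8); b <- b / sum(b)
  m <- (a + b) / 2
  direct <- (sum(a * log(a / m)) + sum(b * log(b / m))) / 2
  expect_equal(jensen_shannon(a, b), direct)
  expect_equal(jensen_shannon(a, b), jensen_shannon(b, a))
  expect_lte(jensen_shannon(a, b), log(2))
  expect_error(jensen_shannon(a, b[1:4]), "support")
  expect_error(jensen_shannon(c(-0.5, 1.5), c(0.5, 0.5)), "negative")
})

test_that("ensemble JS divergence separates and identifies ensembles", {
  ens <- make_continuous_ensemble(M = 10, n_residues = 12, seed = 4)
  expect_equal(ensemble_js_divergence(ens, ens), 0, tolerance = 1e-12)
  ## weights concentrated on members in non-overlapping feature bins
  wa <- c(1, rep(0, 9)); wb <- c(rep(0, 9), 1)
  f <- function(s) s$xyz[1, 1]
  br <- range(vapply(ens$structures, f, 0)) + c(-1e-6, 1e-6)
  br <- c(br[1], mean(br), br[2])
  ja <- ensemble_js_divergence(ens, ens, weights_a = wa, weights_b = wb,
                               feature = f, breaks = br)
  if (abs(ja - log(2)) > 1e-9) {
    ## members 1 and 10 may share a bin for some geometry; force disjoint
    ja <- ensemble_js_divergence(ens, ens, weights_a = wa, weights_b = wb,
                                 feature = function(s) which(vapply(
                                   ens$structures, identical, TRUE, s)),
                                 breaks = c(0.5, 5.5, 10.5))
  }
  expect_equal(ja, log(2), tolerance = 1e-9)
})

test_that("weighted RMSF obeys the closed forms", {
  base <- matrix(c(0, 0, 0, 4, 0, 0, 0, 4, 0, 0, 0, 4, 4, 4, 0, 4, 0, 4,
                   0, 4, 4, 4, 4, 4), ncol = 3, byrow = TRUE)
  s1 <- ens_structure(base, elements = rep("C", 8))
  moved <- base; moved[3, ] <- moved[3, ] + c(2, 0, 0)
  s2 <- ens_structure(moved, elements = rep("C", 8))
  ens <- ensemble_spec(list(s1, s2), labels = c("a", "b"))
  ## all weight on one member: zero fluctuation
  expect_true(all(weighted_rmsf(ens, c(1, 0))$rmsf < 1e-10))
  ## two conformers, one residue displaced 2 A, equal weights, no refit:
  ## sqrt(0.5 * 1^2 + 0.5 * 1^2) = 1 for that residue, 0 elsewhere
  r <- weighted_rmsf(ens, c(0.5, 0.5), fit = FALSE)
  expect_equal(r$rmsf[3], 1)
  expect_true(all(r$rmsf[-3] < 1e-12))
  ## exchangeability: permuting members with their weights changes nothing
  ens_p <- ensemble_spec(list(s2, s1), labels = c("b", "a"))
  expect_equal(weighted_rmsf(ens_p, c(0.7, 0.3), fit = FALSE)$rmsf,
               weighted_rmsf(ens, c(0.3, 0.7), fit = FALSE)$rmsf)
  expect_error(weighted_rmsf(ens, c(0.6, 0.6)), "normalised")
})

test_that("uniform-weight RMSF equals an independently coded unweighted RMSF", {
  ens <- make_continuous_ensemble(M = 6, n_residues = 10, seed = 12)
  M <- 6
  r_w <- weighted_rmsf(ens, rep(1 / M, M))
  ## oracle: plain-mean two-pass superposition and textbook RMSF
  coords <- lapply(ens$structures, function(s) s$xyz)
  mean_xyz <- coords[[1]]
  inds <- seq_len(3 * nrow(mean_xyz))
  for (pass in 1:2) {
    coords <- lapply(coords, function(x) {
      matrix(bio3d::fit.xyz(as.vector(t(mean_xyz)), as.vector(t(x)),
                            fixed.inds = inds, mobile.inds = inds),
             ncol = 3, byrow = TRUE)
    })
    mean_xyz <- Reduce(`+`, coords) / M
  }
  dev2 <- Reduce(`+`, lapply(coords, function(x) rowSums((x - mean_xyz)^2))) / M
  expect_equal(r_w$rmsf, sqrt(dev2), tolerance = 1e-10)
})

test_that("weighted PCA handles rank-1 motion and matches brute-force covariance", {
  base <- matrix(rnorm(30, 0, 4), ncol = 3)
  dir <- c(1, 0, 0)
  structs <- lapply(seq(-2, 2), function(a) {
    x <- base; x[4, ] <- x[4, ] + a * dir
    ens_structure(x, elements = rep("C", 10))
  })
  ens <- ensemble_spec(structs, labels = paste0("m", 1:5))
  pca <- weighted_pca(ens, rep(0.2, 5), n_components = 3, fit = FALSE)
  expect_equal(pca$fraction[1], 1, tolerance = 1e-9)
  ## PC1 parallel to the displacement of residue 4 along x
  v <- pca$vectors[, 1]
  expect_equal(abs(v[10]), 1, tolerance = 1e-9)    # atom 4, x coord = index 10
  ## sign convention: largest-magnitude entry positive
  expect_gt(v[which.max(abs(v))], 0)

  ## brute-force covariance oracle on a generic weighted ensemble
  ens2 <- make_continuous_ensemble(M = 8, n_residues = 8, seed = 3)
  w <- (1:8) / sum(1:8)
  pca2 <- weighted_pca(ens2, w, n_components = 2, fit = FALSE)
  X <- t(vapply(ens2$structures, function(s) as.vector(t(s$xyz)),
                numeric(24)))
  mu <- colSums(X * w)
  C <- matrix(0, 24, 24)
  for (i in 1:8) C <- C + w[i] * tcrossprod(X[i, ] - mu)
  eig <- eigen(C, symmetric = TRUE)
  for (j in 1:2) {
    overlap <- abs(sum(pca2$vectors[, j] * eig$vectors[, j]))
    expect_gte(overlap, 0.999)
  }
  expect_equal(pca2$variance[1:2], eig$values[1:2], tolerance = 1e-8)
  ## uniform weights reduce to unweighted PCA
  pca_u <- weighted_pca(ens2, rep(1 / 8, 8), n_components = 2, fit = FALSE)
  Xc <- scale(X, scale = FALSE)
  eig_u <- eigen(crossprod(Xc) / 8, symmetric = TRUE)
  expect_equal(abs(sum(pca_u$vectors[, 1] * eig_u$vectors[, 1])), 1,
               tolerance = 1e-6)
  expect_error(weighted_pca(ens2, w, n_components = 100), "n_components")
})

test_that("principal modes export as pseudo-trajectory PDB frames", {
  ens <- make_continuous_ensemble(M = 5, n_residues = 8, seed = 6)
  pca <- weighted_pca(ens, rep(0.2, 5))
  p <- withr::local_tempfile(fileext = ".pdb")
  write_mode_pdb(pca, p, mode = 1, n_frames = 3)
  lines <- readLines(p)
  expect_equal(sum(grepl("^MODEL", lines)), 3)
  expect_equal(sum(grepl("^ATOM", lines)), 3 * 8)
})

test_that("structure RMSD is superposition-aware", {
  ens <- make_two_state_ensemble(M = 2, seed = 1, jitter_sd = 0)
  st <- attr(ens, "states")
  ## open vs closed differ by > 4 A even after fitting
  expect_gt(structure_rmsd(st$open, st$closed), 4)
  ## rigid motion of the same structure fits back to ~0
  rot <- st$open
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot$xyz <- sweep(st$open$xyz %*% R, 2, c(5, -3, 2), `+`)
  expect_lt(structure_rmsd(st$open, rot), 1e-6)
})
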