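#' Select the top-weight sub-ensemble
#'
#' Keeps the `ceiling(neff * M)` members with the largest weights (at least
#' 2; ties broken toward the lower member index).
#'
#' @param w weight vector (length M >= 2).
#' @param neff effective sample fraction in (0, 1].
#' @return Sorted integer vector of kept member indices.
#' @export
select_subensemble <- function(w, neff) {
  M <- length(w)
  if (M < 2) stop("sub-ensemble selection needs at least 2 members")
  if (neff <= 0 || neff > 1) stop("neff must lie in (0, 1]")
  k <- min(M, max(2L, as.integer(ceiling(neff * M))))
  ord <- order(-w, seq_along(w))   # stable: lower index wins ties
  sort(ord[seq_len(k)])
}

#' Iterative reweighting: shrink to a minimal sub-ensemble
#'
#' Round 0 is a standard run on the full ensemble. Each subsequent round
#' keeps the `ceiling(Neff * M)` top-weight members, resets them to a
#' uniform prior, rebuilds the voxel selection for the kept model maps, and
#' reruns the full theta scan. Iteration stops when the misfit chi2 (at each
#' round's knee-selected theta) increases - the previous round is returned -
#' or when the selection stops shrinking or reaches the 2-member floor.
#'
#' @param ref reference [density_map], normalised.
#' @param ensemble an [ensemble_spec] (optional when `model_maps` given).
#' @param model_maps optional pre-computed model maps on the reference grid.
#' @param resolution nominal resolution (Angstrom).
#' @param sigma model-map kernel width; default `0.225 * resolution`.
#' @param noise a [noise_model] for the reference threshold.
#' @param ref_threshold optional absolute reference threshold.
#' @param thetas theta grid.
#' @param max_rounds safety cap on the number of shrinking rounds.
#' @return An object of class `iteration_trace`: list with `rounds` (a
#'   data.frame: round, members_kept, theta, chi2, s_kl, neff, cc),
#'   `members` (list of kept index vectors into the full ensemble, one per
#'   round), `final_round` (1-based row of the accepted round), `result`
#'   (the accepted round's `reweight_result`), `final_members` (indices into
#'   the full ensemble), `weights_full` (posterior weights mapped back to
#'   the full ensemble, zero off the final sub-ensemble), `aborted`.
#' @export
iterative_reweight <- function(ref, ensemble = NULL, model_maps = NULL,
                               resolution, sigma = 0.225 * resolution,
                               noise = NULL, ref_threshold = NULL,
                               thetas = default_theta_grid(),
                               max_rounds = 50) {
  if (is.null(model_maps)) {
    if (is.null(ensemble)) stop("supply an ensemble or pre-computed model maps")
    model_maps <- lapply(ensemble$structures, simulate_model_map,
                         grid_of = ref, sigma = sigma)
  }
  M <- length(model_maps)
  if (M < 2) stop("iterative mode needs at least 2 ensemble members")
  labels <- if (!is.null(ensemble)) ensemble$labels
            else sprintf("model_%03d", seq_len(M))

  run_round <- function(keep) {
    res <- reweight_standard(ref, model_maps = model_maps[keep],
                             resolution = resolution, sigma = sigma,
                             noise = noise, ref_threshold = ref_threshold,
                             thetas = thetas)
    res$labels <- labels[keep]
    res
  }

  keep <- seq_len(M)
  rounds <- list()
  members <- list()
  results <- list()
  aborted <- FALSE
  r <- 0L
  repeat {
    res <- tryCatch(run_round(keep), error = function(e) e)
    if (inherits(res, "error")) {
      if (r == 0L) stop(res)
      warning("round ", r, " failed (", conditionMessage(res),
              "); returning the last good round")
      aborted <- TRUE
      break
    }
    r <- r + 1L
    rounds[[r]] <- data.frame(round = r - 1L, members_kept = length(keep),
                              theta = res$theta, chi2 = res$chi2,
                              s_kl = res$s_kl, neff = res$neff, cc = res$cc)
    members[[r]] <- keep
    results[[r]] <- res
    if (r > 1L && res$chi2 > results[[r - 1L]]$chi2) break
    if (r > max_rounds) break
    nxt_local <- select_subensemble(res$weights, res$neff)
    nxt <- keep[nxt_local]
    if (length(nxt) >= length(keep)) break   # no shrink: prior sufficient
    keep <- nxt
  }
  ## accepted round: last one whose chi2 did not increase over its
  ## predecessor (i.e. drop a final degrading round if present)
  final <- length(rounds)
  if (final > 1L && rounds[[final]]$chi2 > rounds[[final - 1L]]$chi2)
    final <- final - 1L
  res <- results[[final]]
  w_full <- numeric(M)
  w_full[members[[final]]] <- res$weights
  structure(list(rounds = do.call(rbind, rounds), members = members,
                 final_round = final, result = res,
                 final_members = members[[final]],
                 weights_full = w_full, labels = labels, aborted = aborted),
            class = "iteration_trace")
}

#' @export
print.iteration_trace <- function(x, ...) {
  cat("Iterative map reweighting\n")
  print(x$rounds, row.names = FALSE)
  n_kept <- length(x$final_members)
  if (n_kept == 2 && nrow(x$rounds) > 1)
    cat("  reached the 2-member floor\n")
  if (nrow(x$rounds) == 1)
    cat("  prior sufficient: the selection did not shrink\n")
  cat(sprintf("  accepted round %d: %d members, chi2 = %.4g, CC = %.4f\n",
              x$final_round - 1L, n_kept, x$result$chi2, x$result$cc))
  invisible(x)
}

#' Write an iteration trace as TSV
#'
#' @param trace an `iteration_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(trace, path) {
  utils::write.table(trace$rounds, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
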