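#' Combined principal component analysis of an aligned trajectory
#'
#' Eigendecomposition of the 3N x 3N covariance of the C-alpha coordinates
#' about the combined mean, computed over every frame of the concatenated
#' trajectory so that all systems share one eigenbasis.  Population (1/F)
#' normalisation is used throughout, so the eigenvalues equal the
#' variances of the corresponding projections exactly.  Each eigenvector
#' is oriented so that its largest-magnitude component is positive
#' (eigenvector signs are otherwise arbitrary), and the observed
#' projection range of the fitted trajectory is stored per PC for
#' pseudo-trajectory construction.
#'
#' @param traj An aligned, combined [trajectory()] with >= 2 frames
#'   (see [align_to_mean()]).
#' @return A `combined_pca` model: `mean` (3N), `lambda` (descending
#'   eigenvalues, Angstrom^2), `vectors` (3N x K orthonormal),
#'   `total_var`, `proj_range` (K x 2), `systems`, `atoms`, `n_frames`.
#' @export
fit_pca <- function(traj) {
  if (!isTRUE(traj$aligned)) {
    abort_state("trajectory must be aligned before PCA (see align_to_mean)")
  }
  if (n_frames(traj) < 2L) abort_invalid("PCA needs at least 2 frames")
  X <- traj$xyz
  F_ <- nrow(X)
  mu <- colMeans(X)
  C <- sweep(X, 2L, mu)
  sv <- svd(C, nu = 0)
  lambda <- sv$d^2 / F_
  V <- sv$v
  # reproducible sign: largest-|component| of each eigenvector positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  proj <- C %*% V
  model <- structure(
    list(mean = mu, lambda = lambda, vectors = V,
         total_var = sum(C^2) / F_,
         proj_range = cbind(min = apply(proj, 2L, min),
                            max = apply(proj, 2L, max)),
         systems = traj$system, atoms = traj$atoms, n_frames = F_),
    class = "combined_pca"
  )
  model
}

#' @export
print.combined_pca <- function(x, ...) {
  k <- min(5L, length(x$lambda))
  cat(sprintf(
    "<combined_pca> %d frames, %d atoms; top eigenvalues (A^2): %s; var explained by PC1-%d: %.1f%%\n",
    x$n_frames, nrow(x$atoms),
    paste(sprintf("%.3g", x$lambda[seq_len(k)]), collapse = ", "), k,
    100 * sum(x$lambda[seq_len(k)]) / x$total_var
  ))
  invisible(x)
}

#' Project trajectory frames onto principal components
#'
#' The projection of a frame is `(frame - mean) . v_i`, in Angstrom;
#' system tags are carried through, which is what makes per-system
#' comparison on the common eigenbasis possible.
#'
#' @param traj A [trajectory()] with the model's atom count.
#' @param model A `combined_pca` from [fit_pca()].
#' @param pcs Integer vector of PC indices (1-based).
#' @return Data frame (`frame`, `system`, `pc`, `projection`), class
#'   `projection_series`.
#' @export
project_trajectory <- function(traj, model, pcs = 1:3) {
  if (ncol(traj$xyz) != length(model$mean)) {
    abort_invalid("trajectory dimension does not match the PCA model")
  }
  if (any(pcs < 1L) || any(pcs > ncol(model$vectors))) {
    abort_invalid("requested PC outside model rank")
  }
  P <- sweep(traj$xyz, 2L, model$mean) %*% model$vectors[, pcs, drop = FALSE]
  out <- data.frame(
    frame = rep(seq_len(nrow(P)), times = length(pcs)),
    system = rep(traj$system, times = length(pcs)),
    pc = rep(as.integer(pcs), each = nrow(P)),
    projection = as.numeric(P),
    stringsAsFactors = FALSE
  )
  class(out) <- c("projection_series", "data.frame")
  out
}

#' Per-system average projection and r.m.s.f. in projection
#'
#' The two diagnostics of the combined analysis: a difference in average
#' projection on a PC means the systems have different average structures
#' along that collective coordinate; a difference in r.m.s.f. means they
#' have different dynamics in that collective motion.  The r.m.s.f. is
#' the standard deviation of the projections about the system's own mean
#' (population normalisation), so the two statistics are independent.
#'
#' @param series A `projection_series` from [project_trajectory()].
#' @return Data frame (`system`, `pc`, `avg_proj`, `rmsf`), Angstrom.
#' @export
system_stats <- function(series) {
  if (anyNA(series$system)) abort_invalid("every frame must carry a system tag")
  groups <- split(series$projection, list(series$system, series$pc), drop = TRUE,
                  sep = "\r")
  keys <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
  out <- data.frame(
    system = keys[, 1L],
    pc = as.integer(keys[, 2L]),
    avg_proj = vapply(groups, mean, 0),
    rmsf = vapply(groups, function(v) sqrt(mean((v - mean(v))^2)), 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$pc, out$system), , drop = FALSE]
}

#' Pseudo-trajectory along one eigenvector
#'
#' Synthetic frames `mean + s_j v_pc` with `s_j` equally spaced over the
#' chosen span visualise the collective motion described by a PC; the
#' first and last frames are the start/end structures used to display the
#' motion's extremes.  Per-residue r.m.s.f. values in the eigenvector are
#' attached (and written to the B-factor column by
#' [write_pseudo_trajectory()]).
#'
#' @param model A `combined_pca`.
#' @param pc PC index.
#' @param n_frames Number of interpolated frames (>= 2).
#' @param span `"observed"` (the projection range of the fitted
#'   trajectory) or `"sigma"` (`+/- k sqrt(lambda)`).
#' @param k Half-width multiplier for `span = "sigma"`.
#' @return A [trajectory()] with attributes `s` (displacements),
#'   `start`/`end` (frame indices) and `residue_rmsf`.
#' @export
pseudo_trajectory <- function(model, pc, n_frames = 20L,
                              span = c("observed", "sigma"), k = 2) {
  span <- match.arg(span)
  if (pc < 1L || pc > ncol(model$vectors)) abort_invalid("pc outside model rank")
  if (n_frames < 2L) abort_invalid("n_frames must be >= 2")
  if (span == "observed") {
    lo <- model$proj_range[pc, "min"]; hi <- model$proj_range[pc, "max"]
    if (hi - lo <= 0) {
      dynsel_abort("zero-variance PC has a degenerate observed span",
                   "dynsel_degenerate_span")
    }
  } else {
    half <- k * sqrt(model$lambda[pc])
    if (half <= 0) {
      dynsel_abort("zero-variance PC has a degenerate span",
                   "dynsel_degenerate_span")
    }
    lo <- -half; hi <- half
  }
  s <- seq(lo, hi, length.out = n_frames)
  X <- outer(s, model$vectors[, pc]) + rep(model$mean, each = n_frames)
  out <- trajectory(model$atoms, X, system = sprintf("pseudo_PC%d", pc),
                    aligned = TRUE)
  attr(out, "s") <- s
  attr(out, "start") <- 1L
  attr(out, "end") <- n_frames
  attr(out, "residue_rmsf") <- residue_rmsf_in_mode(model, pc)
  out
}

#' Write a pseudo-trajectory with mode r.m.s.f. in the B-factor column
#'
#' @param pseudo Output of [pseudo_trajectory()].
#' @param path Output PDB path.
#' @return Invisibly, `path`.
#' @export
write_pseudo_trajectory <- function(pseudo, path) {
  write_trajectory(pseudo, path, b = attr(pseudo, "residue_rmsf"))
}

#' Residue-resolved r.m.s.f. within one eigenvector
#'
#' For residue `r` with eigenvector components `(v_x, v_y, v_z)` the
#' value is `sqrt(lambda_pc) * sqrt(v_x^2 + v_y^2 + v_z^2)`: the
#' root-mean-square displacement of that residue attributable to the
#' collective motion, over the concatenated trajectory.
#'
#' @param model A `combined_pca`.
#' @param pc PC index.
#' @return Numeric vector, one value per residue (Angstrom).
#' @export
residue_rmsf_in_mode <- function(model, pc) {
  if (pc < 1L || pc > ncol(model$vectors)) abort_invalid("pc outside model rank")
  comp <- frame_to_mat(model$vectors[, pc])
  sqrt(model$lambda[pc]) * sqrt(rowSums(comp^2))
}

#' Persist / load a combined PCA model as plain text
#'
#' Writes an eigenvalue table, an eigenvector matrix and the mean
#' structure (PDB) under a common path prefix.
#'
#' @param model A `combined_pca`.
#' @param prefix Path prefix; files `<prefix>_eigenvalues.tsv`,
#'   `<prefix>_eigenvectors.tsv` and `<prefix>_mean.pdb` are produced.
#' @param n_pcs How many PCs to persist.
#' @return Invisibly, the file paths.
#' @export
write_pca_model <- function(model, prefix, n_pcs = 10L) {
  n_pcs <- min(n_pcs, ncol(model$vectors))
  ev <- data.frame(pc = seq_len(n_pcs),
                   lambda_A2 = model$lambda[seq_len(n_pcs)],
                   var_explained = model$lambda[seq_len(n_pcs)] / model$total_var)
  paths <- paste0(prefix, c("_eigenvalues.tsv", "_eigenvectors.tsv", "_mean.pdb"))
  utils::write.table(ev, paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    format(model$vectors[, seq_len(n_pcs), drop = FALSE], digits = 12),
    paths[2L], sep = "\t", quote = FALSE, row.names = FALSE, col.names = paste0("PC", seq_len(n_pcs))
  )
  write_trajectory(trajectory(model$atoms, matrix(model$mean, nrow = 1L),
                              system = "mean", aligned = TRUE), paths[3L])
  invisible(paths)
}
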