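#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD
#' between `R %*% x + t` over the mobile points and the reference points,
#' with the reflection branch of the SVD corrected so `det(R) = +1`
#' always (a mirror image is never "fit" by an improper rotation).
#' Uniform weights are used.
#'
#' @param mobile,reference Numeric n-by-3 coordinate matrices (Angstrom),
#'   n >= 3, matched row by row.
#' @return A `rigid_transform`: list with `rotation` (3x3), `translation`
#'   (length 3) and `rmsd` (Angstrom) after superposition.
#' @export
kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference))) {
    abort_invalid("mobile and reference must have identical dimensions")
  }
  if (nrow(mobile) < 3L || ncol(mobile) != 3L) {
    abort_invalid("coordinate sets must be n x 3 with n >= 3")
  }
  mc <- colMeans(mobile); rc <- colMeans(reference)
  P <- sweep(mobile, 2L, mc)
  Q <- sweep(reference, 2L, rc)
  # Collinear (or coincident) reference/mobile points leave the rotation
  # about the common axis undetermined; rank is read off the cheap 3x3
  # Gram matrices (squared singular values of P and Q).
  if (svd(crossprod(P), nu = 0, nv = 0)$d[2L] < 1e-10 ||
      svd(crossprod(Q), nu = 0, nv = 0)$d[2L] < 1e-10) {
    dynsel_abort("degenerate (collinear) geometry: rotation is not unique",
                 "dynsel_rank_error")
  }
  H <- crossprod(P, Q)           # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- rc - as.numeric(R %*% mc)
  moved <- P %*% t(R) - Q
  structure(
    list(rotation = R, translation = tr, rmsd = sqrt(mean(rowSums(moved^2)))),
    class = "rigid_transform"
  )
}

#' Apply a rigid transform to coordinates
#'
#' @param coords Numeric n-by-3 matrix.
#' @param transform A `rigid_transform` from [kabsch()].
#' @return Transformed n-by-3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  sweep(as.matrix(coords) %*% t(transform$rotation), 2L,
        -transform$translation)
}

#' Iteratively superpose every frame onto the ensemble mean
#'
#' Standard essential-dynamics alignment: frames are superposed onto a
#' running reference (initially the first frame), the mean structure is
#' recomputed, and the cycle repeats until the mean moves by less than
#' `tolerance` (RMSD, Angstrom) or `max_iter` is reached.  The converged
#' mean is the alignment reference stored with the result.
#'
#' @param traj A [trajectory()] with at least one frame.
#' @param tolerance Convergence threshold on the movement of the mean
#'   structure between iterations (Angstrom).
#' @param max_iter Maximum number of mean-refinement iterations.
#' @return The aligned [trajectory()], with attributes `reference` (the
#'   converged mean, n x 3) and `trace` (per-iteration mean displacement).
#' @export
align_to_mean <- function(traj, tolerance = 1e-4, max_iter = 20L) {
  if (n_frames(traj) < 1L) abort_invalid("trajectory has no frames")
  X <- traj$xyz
  na <- n_atoms(traj)
  ref <- frame_to_mat(X[1L, ])
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    for (f in seq_len(nrow(X))) {
      m <- frame_to_mat(X[f, ])
      X[f, ] <- mat_to_frame(apply_transform(m, kabsch(m, ref)))
    }
    new_ref <- frame_to_mat(colMeans(X))
    delta <- coord_rmsd(new_ref, ref)
    trace <- c(trace, delta)
    ref <- new_ref
    if (delta < tolerance) break
  }
  if (trace[length(trace)] >= tolerance) {
    warning(sprintf(
      "alignment did not converge in %d iterations (last mean shift %.3g A)",
      max_iter, trace[length(trace)]
    ))
  }
  out <- trajectory(traj$atoms, X, system = traj$system, aligned = TRUE)
  attr(out, "reference") <- ref
  attr(out, "trace") <- trace
  out
}
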