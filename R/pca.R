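# Principal component analysis of positional thermal fluctuations.
#
# Frames are first superposed (Kabsch) onto an iteratively refined mean
# structure, removing overall translation/rotation so that what remains is
# internal fluctuation.  The 3N x 3N variance-covariance matrix over the
# analysis selection (Calpha atoms, typically) is then diagonalized; the
# eigenvectors are the principal modes, collective motions ordered by
# fluctuation amplitude.  When snapshot weights from aMD reweighting are
# supplied, the mean and covariance are weighted accordingly.

#' Iteratively align trajectory frames onto their mean
#'
#' Each frame is rigid-body superposed (unweighted Kabsch on the fit
#' selection) onto the running mean structure; the mean is recomputed and
#' the process repeats until the mean moves < `tol` (mean per-atom
#' displacement, Angstrom) or `max_iter` is hit.
#'
#' @param traj `md_trajectory` with >= 2 frames.
#' @param fit_selection selection used for the superposition (default: all
#'   atoms).
#' @param weights optional per-frame weights for the mean.
#' @param tol convergence threshold on the mean displacement, Angstrom.
#' @param max_iter iteration cap; non-convergence is an error.
#' @return List: `trajectory` (aligned `md_trajectory`), `mean` (N x 3
#'   matrix), `iterations`.
#' @export
align_frames <- function(traj, fit_selection = NULL, weights = NULL,
                         tol = 1e-6, max_iter = 50) {
  stopifnot(inherits(traj, "md_trajectory"))
  nf <- n_frames(traj)
  if (nf < 2) stop("need >= 2 frames to align")
  na <- nrow(traj$atom)
  fit_idx <- if (is.null(fit_selection)) seq_len(na)
             else resolve_selection(traj, fit_selection)
  if (is.null(weights)) weights <- rep(1, nf)
  w <- weights / sum(weights)

  xyz <- traj$xyz
  frame_mat <- function(row) matrix(row, ncol = 3, byrow = TRUE)
  mean_coord <- frame_mat(colSums(xyz * w))
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(nf)) {
      fr <- frame_mat(xyz[i, ])
      tr <- kabsch_superpose(fr[fit_idx, , drop = FALSE],
                             mean_coord[fit_idx, , drop = FALSE])
      xyz[i, ] <- as.vector(t(apply_transform(fr, tr)))
    }
    new_mean <- frame_mat(colSums(xyz * w))
    shift <- mean(sqrt(rowSums((new_mean - mean_coord)^2)))
    mean_coord <- new_mean
    if (shift < tol)
      return(list(trajectory = md_trajectory(traj$atom, xyz,
                                             times = traj$times,
                                             delta_v = traj$delta_v),
                  mean = mean_coord, iterations = iter))
  }
  stop("frame alignment did not converge in ", max_iter,
       " iterations (last mean shift ", signif(shift, 3), " A)")
}

#' Positional variance-covariance matrix of an aligned trajectory
#'
#' C = sum_t w_t (x_t - xbar)(x_t - xbar)^T over the 3N coordinates of the
#' analysis selection, with the weighted mean xbar.  Symmetric positive
#' semi-definite by construction.
#'
#' @param aligned an aligned `md_trajectory` (see [align_frames()]).
#' @param analysis_selection atoms entering the covariance (default: all
#'   atoms named "CA").
#' @param weights optional per-frame snapshot weights.
#' @return 3N x 3N matrix (Angstrom^2) with attributes `mean` (3N vector)
#'   and `atom_indices`.
#' @export
covariance_matrix <- function(aligned, analysis_selection = NULL,
                              weights = NULL) {
  stopifnot(inherits(aligned, "md_trajectory"))
  idx <- if (is.null(analysis_selection)) {
    which(aligned$atom$atom_name == "CA")
  } else resolve_selection(aligned, analysis_selection)
  if (length(idx) == 0) stop("empty analysis selection")
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  x <- aligned$xyz[, cols, drop = FALSE]
  nf <- nrow(x)
  if (is.null(weights)) weights <- rep(1, nf)
  w <- weights / sum(weights)
  xbar <- colSums(x * w)
  xc <- sweep(x, 2, xbar)
  cov <- crossprod(xc * sqrt(w), xc * sqrt(w))
  cov <- (cov + t(cov)) / 2
  attr(cov, "mean") <- xbar
  attr(cov, "atom_indices") <- idx
  cov
}

#' Principal modes of a covariance matrix
#'
#' Eigenpairs sorted by descending eigenvalue with a deterministic sign
#' convention: the largest-magnitude component of each mode is positive.
#' Mode vectors are unit norm; eigenvalues are in Angstrom^2 and their sum
#' equals the total mean-square fluctuation (the trace).
#'
#' @param covariance matrix from [covariance_matrix()] (any symmetric
#'   matrix accepted).
#' @param k number of modes to return (<= 3N).
#' @return Object of class `principal_modes`: `values` (length k),
#'   `vectors` (3N x k), `mean` (carried over when present).
#' @export
principal_modes <- function(covariance, k = 3) {
  stopifnot(is.matrix(covariance), nrow(covariance) == ncol(covariance))
  if (max(abs(covariance - t(covariance))) > 1e-8 * max(1, max(abs(covariance))))
    stop("covariance matrix is not symmetric")
  n <- nrow(covariance)
  if (k > n) stop("k = ", k, " exceeds matrix dimension ", n)
  e <- eigen(covariance, symmetric = TRUE)
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(vec[, j]))
    if (vec[i_max, j] < 0) vec[, j] <- -vec[, j]
  }
  structure(list(values = e$values[seq_len(k)], vectors = vec,
                 all_values = e$values,
                 mean = attr(covariance, "mean"),
                 atom_indices = attr(covariance, "atom_indices")),
            class = "principal_modes")
}

#' Project aligned frames onto a principal mode
#'
#' Dot product of each frame's displacement from the mean with the unit
#' mode vector; the variance of the projection onto mode i estimates
#' eigenvalue i.
#'
#' @param aligned aligned `md_trajectory` (same topology the covariance was
#'   computed on).
#' @param modes a [principal_modes()] object carrying its mean and atom
#'   indices.
#' @param mode which mode to project onto (1-based).
#' @return Numeric per-frame series (Angstrom).
#' @export
project_mode <- function(aligned, modes, mode = 1) {
  stopifnot(inherits(modes, "principal_modes"))
  idx <- modes$atom_indices
  if (is.null(idx) || is.null(modes$mean))
    stop("modes object lacks mean/atom indices; compute it via covariance_matrix")
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  xc <- sweep(aligned$xyz[, cols, drop = FALSE], 2, modes$mean)
  as.numeric(xc %*% modes$vectors[, mode])
}

#' Write a mode-arrow pseudo-PDB for visualization
#'
#' MODEL 1 holds the mean structure of the analysis selection; MODEL 2 the
#' mean displaced by +sqrt(eigenvalue) along the mode, so viewers can draw
#' the collective motion as inter-model vectors.  (Mode vectors in the data
#' model stay unit norm; the sqrt-eigenvalue scaling is for display only.)
#'
#' @param aligned aligned trajectory providing the topology.
#' @param modes [principal_modes()] object.
#' @param mode mode index.
#' @param path output PDB path.
#' @export
write_mode_arrows <- function(aligned, modes, mode, path) {
  idx <- modes$atom_indices
  at <- aligned$atom[idx, , drop = FALSE]
  disp <- sqrt(modes$values[mode]) * modes$vectors[, mode]
  xyz <- rbind(modes$mean, modes$mean + disp)
  write_pdb(md_trajectory(at, xyz, times = c(0, 1)), path)
}
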