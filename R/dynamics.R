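#' Kabsch least-squares superposition
#'
#' Finds the proper rigid transform (rotation + translation, reflections
#' excluded) minimising the (optionally weighted) sum of squared deviations
#' between `mobile` and `reference`, via SVD of the cross-covariance with
#' the usual determinant correction.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3, not
#'   collinear.
#' @param weights optional non-negative per-point weights.
#' @return list with `transform` (an [rigid_transform()] mapping mobile
#'   onto reference) and `rmsd` (Angstrom, weighted root-mean-square
#'   deviation after superposition).
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference) || ncol(mobile) != 3L || ncol(reference) != 3L) {
    stop("superpose: coordinate sets must be equal-size n x 3 matrices")
  }
  if (n < 3L) stop("superpose: at least 3 points required")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("superpose: weights must be non-negative with positive sum")
  }
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  # collinearity check: the centered reference must span >= 2 dimensions
  sB <- svd(B)$d
  if (sB[2] < 1e-10 * max(1, sB[1])) {
    stop("superpose: degenerate (collinear) geometry")
  }
  H <- t(A * w) %*% B                      # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cr - as.numeric(R %*% cm)
  xf <- rigid_transform(R, t_vec)
  fitted <- apply_transform(xf, mobile)
  rmsd <- sqrt(sum(w * rowSums((fitted - reference)^2)))
  list(transform = xf, rmsd = rmsd)
}

#' Plain RMSD between two coordinate sets (no fitting)
#' @param a,b n x 3 matrices.
#' @export
rmsd_raw <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

#' Per-frame RMSD series of a trajectory
#'
#' Each frame is superposed onto the reference frame over the selection;
#' the RMSD over that selection after fitting is reported. The series is 0
#' at the reference frame by construction.
#'
#' @param traj an `xl_trajectory`.
#' @param reference reference frame index (default 1).
#' @param sel an [atom_selection()] (default: CA atoms).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference = 1L,
                        sel = atom_selection(element_class = "calpha")) {
  stopifnot(inherits(traj, "xl_trajectory"))
  idx <- select_atoms(traj, sel)
  if (!length(idx)) stop("rmsd_series: selection matches no atoms")
  ref <- traj$frames[[reference]][idx, , drop = FALSE]
  vapply(traj$frames, function(f) {
    superpose(f[idx, , drop = FALSE], ref)$rmsd
  }, 0)
}

#' Per-atom root-mean-square fluctuation
#'
#' Two-pass procedure: frames are first superposed onto a provisional
#' reference (frame 1), the mean structure is computed, and all frames are
#' re-superposed onto that mean; RMSF_i is then the root-mean-square
#' displacement of atom i about its mean position. `reference = "first"`
#' skips the second pass and fluctuates about frame 1 instead.
#'
#' @param traj an `xl_trajectory` with >= 2 frames.
#' @param sel an [atom_selection()] (default: CA atoms).
#' @param reference `"mean"` (default, two-pass) or `"first"`.
#' @return numeric vector of per-atom RMSF (Angstrom) over the selection,
#'   named by `chain:resno:atom`.
#' @export
rmsf <- function(traj, sel = atom_selection(element_class = "calpha"),
                 reference = c("mean", "first")) {
  stopifnot(inherits(traj, "xl_trajectory"))
  reference <- match.arg(reference)
  if (n_frames(traj) < 2L) stop("rmsf: at least 2 frames required")
  idx <- select_atoms(traj, sel)
  if (!length(idx)) stop("rmsf: selection matches no atoms")
  sub <- lapply(traj$frames, function(f) f[idx, , drop = FALSE])
  fitted <- fit_frames(sub, sub[[1]])
  center <- if (reference == "mean") {
    m <- Reduce(`+`, fitted) / length(fitted)
    fitted <- fit_frames(sub, m)
    Reduce(`+`, fitted) / length(fitted)
  } else {
    sub[[1]]
  }
  dev2 <- lapply(fitted, function(f) rowSums((f - center)^2))
  out <- sqrt(Reduce(`+`, dev2) / length(dev2))
  at <- traj$topology$atoms[idx, ]
  names(out) <- paste(at$chain_id, at$seq_num, at$atom_name, sep = ":")
  out
}

# superpose every frame onto a common reference
fit_frames <- function(frames, ref) {
  lapply(frames, function(f) apply_transform(superpose(f, ref)$transform, f))
}
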