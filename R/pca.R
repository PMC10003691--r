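#' Principal component analysis of a trajectory
#'
#' Frames are superposed onto their mean structure over the selection
#' (two-pass fit, as for RMSF) to remove rigid-body motion; the remaining
#' positional covariance is then decomposed. Components carry a
#' deterministic sign convention — the coefficient of largest magnitude is
#' made positive — so projections are stable across runs. Explained
#' variances are non-increasing and sum (over the full rank) to the total
#' superposed positional variance.
#'
#' @param traj an `xl_trajectory` with at least 2 frames (3 or more for a
#'   meaningful decomposition).
#' @param sel an [atom_selection()] (default: CA atoms).
#' @param n_components number of components to report (default 3).
#' @return list of class `xl_pca`: `components` (3N x n_components,
#'   orthonormal columns), `explained_variance` (full spectrum,
#'   non-increasing), `projections` (frames x n_components),
#'   `total_variance`.
#' @export
pca_projection <- function(traj, sel = atom_selection(element_class = "calpha"),
                           n_components = 3L) {
  stopifnot(inherits(traj, "xl_trajectory"))
  if (n_frames(traj) < 2L) stop("pca_projection: at least 2 frames required")
  idx <- select_atoms(traj, sel)
  if (!length(idx)) stop("pca_projection: selection matches no atoms")
  sub <- lapply(traj$frames, function(f) f[idx, , drop = FALSE])
  fitted <- fit_frames(sub, sub[[1]])
  m <- Reduce(`+`, fitted) / length(fitted)
  fitted <- fit_frames(sub, m)
  m <- Reduce(`+`, fitted) / length(fitted)

  X <- t(vapply(fitted, function(f) as.vector(t(f)), numeric(3 * length(idx))))
  Xc <- sweep(X, 2, as.vector(t(m)))
  pc <- stats::prcomp(Xc, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  n_components <- min(n_components, ncol(pc$rotation))
  comps <- pc$rotation[, seq_len(n_components), drop = FALSE]
  proj <- pc$x[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(n_components)) {
    peak <- which.max(abs(comps[, k]))
    if (comps[peak, k] < 0) {
      comps[, k] <- -comps[, k]
      proj[, k] <- -proj[, k]
    }
  }
  out <- list(components = comps,
              explained_variance = ev,
              projections = proj,
              total_variance = sum(Xc^2) / (nrow(Xc) - 1))
  class(out) <- "xl_pca"
  out
}

#' @export
print.xl_pca <- function(x, ...) {
  k <- ncol(x$components)
  frac <- x$explained_variance[seq_len(k)] / max(sum(x$explained_variance), .Machine$double.eps)
  cat(sprintf("<xl_pca> %d frames, %d components reported (%s of variance)\n",
              nrow(x$projections), k,
              paste(sprintf("%.1f%%", 100 * frac), collapse = ", ")))
  invisible(x)
}
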