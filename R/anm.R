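#' Anisotropic network model normal modes
#'
#' Builds the 3N x 3N ANM Hessian over CA atoms — uniform springs of
#' stiffness `gamma` between every CA pair within `cutoff` — and
#' diagonalises it. For a connected, non-degenerate structure the six
#' smallest eigenvalues are numerically zero (rigid-body translations and
#' rotations); the low-frequency non-trivial modes that follow describe
#' collective motions such as hinge bending.
#'
#' Eigenvalues are returned ascending; eigenvectors are orthonormal.
#' Eigenvalues below `1e-8 x` the largest are flagged as the rigid-body
#' null space. A node with no neighbour leaves extra zero modes; this is
#' reported with a warning rather than hidden.
#'
#' @param s an `xl_structure` or `xl_assembly`.
#' @param cutoff spring cutoff between CA atoms, Angstrom (default 15).
#' @param gamma uniform spring constant (default 1; arbitrary units, sets
#'   the eigenvalue scale only).
#' @return list of class `xl_modes`: `values` (ascending), `vectors`
#'   (columns, orthonormal), `n_zero`, `cutoff`, `gamma`, `ca_coords`,
#'   `ca_atoms` (atom table rows of the network nodes).
#' @export
anm_modes <- function(s, cutoff = 15, gamma = 1) {
  if (inherits(s, "xl_assembly")) {
    idx <- which(s$atoms$atom_name == "CA")
    xyz <- s$coords[idx, , drop = FALSE]
    at <- s$atoms[idx, ]
  } else {
    stopifnot(inherits(s, "xl_structure"))
    idx <- which(s$atoms$atom_name == "CA")
    xyz <- s$coords[[1]][idx, , drop = FALSE]
    at <- s$atoms[idx, ]
  }
  n <- nrow(xyz)
  if (n < 3L) stop("anm_modes: at least 3 CA atoms required")
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  adj <- d2 <= cutoff^2 & d2 > 1e-12
  if (any(rowSums(adj) == 0)) {
    warning("anm_modes: network is disconnected (isolated node); ",
            "extra zero modes will be present")
  }
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1L)) {
    js <- which(adj[i, ] & seq_len(n) > i)
    for (j in js) {
      dv <- xyz[j, ] - xyz[i, ]
      blk <- -gamma * tcrossprod(dv) / sum(dv^2)
      ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
      H[ri, rj] <- blk
      H[rj, ri] <- blk
      H[ri, ri] <- H[ri, ri] - blk
      H[rj, rj] <- H[rj, rj] - blk
    }
  }
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(eig$values)
  values <- pmax(eig$values[ord], 0)
  vectors <- eig$vectors[, ord, drop = FALSE]
  n_zero <- sum(values < 1e-8 * max(values))
  out <- list(values = values, vectors = vectors, n_zero = n_zero,
              cutoff = cutoff, gamma = gamma,
              ca_coords = xyz, ca_atoms = at)
  class(out) <- "xl_modes"
  out
}

#' @export
print.xl_modes <- function(x, ...) {
  nt <- length(x$values) - x$n_zero
  cat(sprintf("<xl_modes> %d nodes, %d zero (rigid-body) modes, %d non-trivial modes; lowest non-trivial eigenvalue %.4g\n",
              nrow(x$ca_coords), x$n_zero, nt,
              if (nt) x$values[x$n_zero + 1] else NA))
  invisible(x)
}

#' Non-trivial mode index helper
#'
#' Maps "k-th non-trivial mode" to an absolute index into the mode set
#' (skipping the rigid-body null space).
#'
#' @param modes an `xl_modes`.
#' @param k which non-trivial mode (1 = lowest-frequency internal motion).
#' @export
nontrivial_mode <- function(modes, k = 1L) modes$n_zero + k

#' Animate a normal mode as a trajectory
#'
#' Generates `n_frames` frames of the CA network displaced along one
#' eigenvector: frame k is `equilibrium + amplitude * sin(2*pi*k/n_frames)
#' * eigenvector` (k = 0 .. n_frames-1), so the animation starts at the
#' equilibrium and frames k and n_frames-k mirror about it.
#'
#' @param modes an `xl_modes`.
#' @param mode absolute mode index (ascending order). Rigid-body modes
#'   (index <= `n_zero`) are refused.
#' @param amplitude displacement amplitude, Angstrom.
#' @param n_frames number of frames over one period.
#' @return an `xl_trajectory` over the CA-only topology.
#' @export
mode_trajectory <- function(modes, mode, amplitude, n_frames = 20L) {
  stopifnot(inherits(modes, "xl_modes"))
  if (mode < 1L || mode > length(modes$values)) {
    stop("mode_trajectory: mode index out of range")
  }
  if (mode <= modes$n_zero) {
    stop("mode_trajectory: mode ", mode,
         " is a rigid-body mode; pick an index > n_zero (",
         modes$n_zero, ")")
  }
  n <- nrow(modes$ca_coords)
  vec <- matrix(modes$vectors[, mode], ncol = 3, byrow = TRUE)
  at <- modes$ca_atoms
  at$serial <- seq_len(n)
  at <- at[, c("serial", "atom_name", "element", "res_name", "chain_id",
               "seq_num", "icode", "occupancy", "bfactor", "is_hetero")]
  topo <- xl_structure(at, modes$ca_coords, title = "mode animation")
  frames <- lapply(seq_len(n_frames) - 1L, function(k) {
    modes$ca_coords + amplitude * sin(2 * pi * k / n_frames) * vec
  })
  xl_trajectory(topo, frames)
}

#' Write a mode set as text
#'
#' One block per mode: eigenvalue then the 3N eigenvector components.
#'
#' @param modes an `xl_modes`.
#' @param path output path.
#' @param n_modes how many non-trivial modes to write (default all).
#' @export
write_modes <- function(modes, path, n_modes = NULL) {
  nt <- length(modes$values) - modes$n_zero
  if (is.null(n_modes)) n_modes <- nt
  n_modes <- min(n_modes, nt)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_modes)) {
    i <- modes$n_zero + k
    writeLines(sprintf("MODE %d EIGENVALUE %.10g", k, modes$values[i]), con)
    writeLines(paste(sprintf("%.8f", modes$vectors[, i]), collapse = " "), con)
  }
  invisible(path)
}
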