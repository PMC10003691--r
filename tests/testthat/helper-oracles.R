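# Independent oracles used to cross-check the package's implementations.
# Each deliberately takes a different computational route than the code it
# validates.

# Horn's quaternion method: closed-form optimal-superposition RMSD from the
# largest eigenvalue of the 4x4 key matrix. No SVD, no explicit rotation.
quaternion_rmsd <- function(mobile, reference) {
  A <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  B <- sweep(as.matrix(reference), 2, colMeans(reference))
  S <- t(A) %*% B
  K <- matrix(c(
    S[1,1] + S[2,2] + S[3,3], S[2,3] - S[3,2], S[3,1] - S[1,3], S[1,2] - S[2,1],
    S[2,3] - S[3,2], S[1,1] - S[2,2] - S[3,3], S[1,2] + S[2,1], S[1,3] + S[3,1],
    S[3,1] - S[1,3], S[1,2] + S[2,1], -S[1,1] + S[2,2] - S[3,3], S[2,3] + S[3,2],
    S[1,2] - S[2,1], S[1,3] + S[3,1], S[2,3] + S[3,2], -S[1,1] - S[2,2] + S[3,3]
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lambda) / nrow(A)
  sqrt(max(0, msd))
}

# Exhaustive Lance-Williams agglomeration under Ward's criterion, tracking
# cluster memberships. Works on squared Euclidean distances; returns the
# k-cluster labels (renumbered by first appearance).
ward_oracle_labels <- function(features, k) {
  features <- as.matrix(features)
  n <- nrow(features)
  d2 <- as.matrix(stats::dist(features))^2
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  D <- d2
  diag(D) <- Inf
  while (length(active) > k) {
    m <- length(active)
    # find the minimal Ward merge cost among active clusters
    best <- c(NA, NA); bestval <- Inf
    for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
      if (D[i, j] < bestval) { bestval <- D[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    ni <- sizes[i]; nj <- sizes[j]
    newD <- rep(Inf, m)
    for (h in seq_len(m)) {
      if (h == i || h == j) next
      nh <- sizes[h]
      newD[h] <- ((ni + nh) * D[i, h] + (nj + nh) * D[j, h] -
                  nh * D[i, j]) / (ni + nj + nh)
    }
    active[[i]] <- c(active[[i]], active[[j]])
    sizes[i] <- ni + nj
    D[i, ] <- newD; D[, i] <- newD; D[i, i] <- Inf
    active <- active[-j]; sizes <- sizes[-j]
    D <- D[-j, -j, drop = FALSE]
  }
  labels <- integer(n)
  for (c in seq_along(active)) labels[active[[c]]] <- c
  labels
}

# Ward must start from mutual squared distances scaled as hclust ward.D2
# expects: D initialised to squared Euclidean distances (merge cost for
# singletons is d^2/2 up to a constant factor, which does not change the
# argmin sequence).

# agreement of two flat clusterings up to label permutation
same_partition <- function(a, b) {
  identical(unname(as.integer(factor(a, levels = unique(a)))),
            unname(as.integer(factor(b, levels = unique(b)))))
}

# brute-force minimum CA-CA distance for one cross-link on an assembly:
# scans every CA atom pair whose chains belong to the two proteins
bruteforce_min_distance <- function(assembly, res_a, res_b,
                                    chains_a, chains_b) {
  at <- assembly$atoms
  xy <- assembly$coords
  ia <- which(at$atom_name == "CA" & at$seq_num == res_a &
              at$chain_label %in% chains_a)
  ib <- which(at$atom_name == "CA" & at$seq_num == res_b &
              at$chain_label %in% chains_b)
  best <- Inf
  for (i in ia) for (j in ib) {
    if (i == j) next
    best <- min(best, sqrt(sum((xy[i, ] - xy[j, ])^2)))
  }
  best
}

# dense elementwise ANM Hessian (scalar loops, no block arithmetic)
anm_oracle_spectrum <- function(xyz, cutoff = 15, gamma = 1) {
  n <- nrow(xyz)
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dv <- xyz[j, ] - xyz[i, ]
    r2 <- sum(dv^2)
    if (r2 > cutoff^2) next
    for (a in 1:3) for (b in 1:3) {
      val <- -gamma * dv[a] * dv[b] / r2
      H[3 * (i - 1) + a, 3 * (j - 1) + b] <- val
      H[3 * (i - 1) + a, 3 * (i - 1) + b] <-
        H[3 * (i - 1) + a, 3 * (i - 1) + b] - val
    }
  }
  sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
}

# direct covariance eigendecomposition for trajectory PCA (no prcomp)
pca_oracle <- function(frames_matrix) {
  Xc <- sweep(frames_matrix, 2, colMeans(frames_matrix))
  C <- crossprod(Xc) / (nrow(Xc) - 1)
  eig <- eigen(C, symmetric = TRUE)
  list(values = eig$values, vectors = eig$vectors)
}

# exhaustive all-pairs native-contact scan (no centroid prefilter)
contacts_oracle <- function(topology, coords, cutoff = 4.5, min_seq_sep = 3) {
  at <- topology$atoms
  heavy <- which(at$element != "H")
  key <- paste(at$chain_id[heavy], at$seq_num[heavy], at$icode[heavy])
  res <- split(heavy, key)
  first <- vapply(res, `[[`, 0L, 1L)
  ord <- order(at$chain_id[first], at$seq_num[first], at$icode[first])
  res <- res[ord]; first <- first[ord]
  out <- list(); n <- 0L
  for (i in seq_len(length(res) - 1L)) for (j in seq(i + 1L, length(res))) {
    ci <- at$chain_id[first[i]]; cj <- at$chain_id[first[j]]
    si <- at$seq_num[first[i]]; sj <- at$seq_num[first[j]]
    if (ci == cj && abs(si - sj) < min_seq_sep) next
    best <- Inf
    for (p in res[[i]]) for (q in res[[j]]) {
      best <- min(best, sum((coords[p, ] - coords[q, ])^2))
    }
    if (sqrt(best) <= cutoff) {
      n <- n + 1L
      out[[n]] <- c(i, j, sqrt(best))
    }
  }
  if (!n) return(matrix(numeric(0), 0, 3))
  do.call(rbind, out)
}
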