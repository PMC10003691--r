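# Residue-level contact analyses: native contacts, Q, contact maps,
# hydrogen-bond occupancy. All distances are minimum heavy-atom distances
# between residues, in Angstrom.

# residue bookkeeping: returns a list of heavy-atom index vectors, one per
# residue, plus a residue table in deterministic order
residue_index <- function(topology, atom_idx = NULL) {
  at <- topology$atoms
  if (is.null(atom_idx)) atom_idx <- seq_len(nrow(at))
  atom_idx <- atom_idx[at$element[atom_idx] != "H"]
  key <- paste(at$chain_id[atom_idx], at$seq_num[atom_idx], at$icode[atom_idx],
               sep = "|")
  split_idx <- split(atom_idx, key)
  first <- vapply(split_idx, `[[`, 0L, 1L)
  ord <- order(at$chain_id[first], at$seq_num[first], at$icode[first])
  split_idx <- split_idx[ord]
  first <- first[ord]
  list(
    atoms = split_idx,
    table = data.frame(chain_id = at$chain_id[first],
                       seq_num = at$seq_num[first],
                       icode = at$icode[first],
                       res_name = at$res_name[first],
                       stringsAsFactors = FALSE)
  )
}

# minimum heavy-atom distance between two atom-index sets in one frame
min_pair_distance <- function(coords, ia, ib) {
  xa <- coords[ia, , drop = FALSE]
  xb <- coords[ib, , drop = FALSE]
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(max(0, min(d2)))
}

#' Native contacts of a reference conformation
#'
#' A residue pair (i, j) is a native contact when the minimum heavy-atom
#' distance in the reference frame is within `cutoff` and, for residues of
#' the same chain, the sequence separation is at least `min_seq_sep`
#' (short-range neighbours are always in contact and carry no structural
#' signal). The native state here is simply the chosen frame — typically
#' the starting conformation of a simulation.
#'
#' @param x an `xl_structure` or `xl_trajectory`.
#' @param frame reference frame/model index (default 1).
#' @param cutoff heavy-atom distance cutoff, Angstrom (default 4.5).
#' @param min_seq_sep minimum |i - j| for intra-chain pairs (default 3).
#' @param scope count `"intra"`-chain pairs, `"inter"`-chain pairs, or
#'   `"both"` (default).
#' @return data frame of class `xl_contacts`: one row per contact with
#'   chains, residue numbers and the native distance; attributes `cutoff`,
#'   `min_seq_sep`, `pairs` (atom-index pairs for re-evaluation) and
#'   `residues`.
#' @export
native_contacts <- function(x, frame = 1L, cutoff = 4.5, min_seq_sep = 3L,
                            scope = c("both", "intra", "inter")) {
  scope <- match.arg(scope)
  topo <- if (inherits(x, "xl_trajectory")) x$topology else x
  coords <- coords_of(x, frame)
  ri <- residue_index(topo)
  nres <- length(ri$atoms)
  cent <- t(vapply(ri$atoms, function(ia) colMeans(coords[ia, , drop = FALSE]),
                   numeric(3)))
  radius <- vapply(seq_len(nres), function(i) {
    sqrt(max(rowSums((coords[ri$atoms[[i]], , drop = FALSE] -
                      matrix(cent[i, ], length(ri$atoms[[i]]), 3,
                             byrow = TRUE))^2)))
  }, 0)
  reach <- cutoff + outer(radius, radius, "+")
  cd2 <- outer(rowSums(cent^2), rowSums(cent^2), "+") - 2 * cent %*% t(cent)

  rows <- list(); pairs <- list(); n <- 0L
  for (i in seq_len(nres - 1L)) {
    for (j in seq(i + 1L, nres)) {
      same_chain <- ri$table$chain_id[i] == ri$table$chain_id[j]
      if (scope == "intra" && !same_chain) next
      if (scope == "inter" && same_chain) next
      if (same_chain &&
          abs(ri$table$seq_num[i] - ri$table$seq_num[j]) < min_seq_sep) next
      if (cd2[i, j] > reach[i, j]^2) next     # centroid prefilter
      d <- min_pair_distance(coords, ri$atoms[[i]], ri$atoms[[j]])
      if (d <= cutoff) {
        n <- n + 1L
        rows[[n]] <- data.frame(
          chain_i = ri$table$chain_id[i], res_i = ri$table$seq_num[i],
          chain_j = ri$table$chain_id[j], res_j = ri$table$seq_num[j],
          distance = d, stringsAsFactors = FALSE)
        pairs[[n]] <- list(ri$atoms[[i]], ri$atoms[[j]])
      }
    }
  }
  out <- if (n) do.call(rbind, rows) else
    data.frame(chain_i = character(), res_i = integer(),
               chain_j = character(), res_j = integer(), distance = numeric())
  attr(out, "cutoff") <- cutoff
  attr(out, "min_seq_sep") <- min_seq_sep
  attr(out, "pairs") <- pairs
  class(out) <- c("xl_contacts", "data.frame")
  out
}

#' Fraction of native contacts over a trajectory
#'
#' Q(f) is the fraction of native pairs whose minimum heavy-atom distance
#' in frame f is within `tolerance * cutoff`. With contacts built from
#' frame 1, Q(1) = 1 by construction; transitions away from the native
#' state show up as a drop in Q.
#'
#' @param traj an `xl_trajectory`.
#' @param contacts an `xl_contacts` set from [native_contacts()].
#' @param tolerance multiplicative tolerance on the cutoff (default 1.0).
#' @return numeric vector, Q in [0, 1] per frame.
#' @export
q_series <- function(traj, contacts, tolerance = 1.0) {
  stopifnot(inherits(traj, "xl_trajectory"), inherits(contacts, "xl_contacts"))
  pairs <- attr(contacts, "pairs")
  if (!length(pairs)) stop("q_series: empty contact set")
  thr <- tolerance * attr(contacts, "cutoff")
  vapply(traj$frames, function(f) {
    d <- vapply(pairs, function(p) min_pair_distance(f, p[[1]], p[[2]]), 0)
    mean(d <= thr)
  }, 0)
}

#' Residue-residue contact frequency map
#'
#' Entry (i, j) is the fraction of frames in which residue i of `group_a`
#' and residue j of `group_b` have minimum heavy-atom distance within
#' `cutoff`. With identical groups the matrix is symmetric.
#'
#' @param traj an `xl_trajectory`.
#' @param group_a,group_b [atom_selection()]s defining the two residue
#'   groups.
#' @param cutoff heavy-atom distance cutoff, Angstrom (default 4.5).
#' @return numeric matrix (rows = `group_a` residues, cols = `group_b`
#'   residues) with `chain:resno` dimnames.
#' @export
contact_map <- function(traj, group_a, group_b, cutoff = 4.5) {
  stopifnot(inherits(traj, "xl_trajectory"))
  ia <- select_atoms(traj, group_a)
  ib <- select_atoms(traj, group_b)
  if (!length(ia) || !length(ib)) stop("contact_map: empty selection")
  ra <- residue_index(traj$topology, ia)
  rb <- residue_index(traj$topology, ib)
  acc <- matrix(0, length(ra$atoms), length(rb$atoms))
  for (f in traj$frames) {
    for (i in seq_along(ra$atoms)) {
      for (j in seq_along(rb$atoms)) {
        acc[i, j] <- acc[i, j] +
          (min_pair_distance(f, ra$atoms[[i]], rb$atoms[[j]]) <= cutoff)
      }
    }
  }
  acc <- acc / length(traj$frames)
  dimnames(acc) <- list(paste0(ra$table$chain_id, ":", ra$table$seq_num),
                        paste0(rb$table$chain_id, ":", rb$table$seq_num))
  acc
}

#' Write a contact map as delimited text
#' @param map matrix from [contact_map()].
#' @param path output path.
#' @export
write_contact_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Hydrogen-bond occupancy census
#'
#' Scans donor-acceptor (N/O) pairs across a two-group partition over all
#' frames. When hydrogens are present on a donor (any H within 1.2 A in
#' the topology frame), the criterion is donor-acceptor distance within
#' `dist_cutoff` and D-H...A angle at least `angle_cutoff`; without
#' hydrogens the distance criterion alone is used (the usual fallback for
#' heavy-atom-only models). Pairs within one residue are skipped. Records
#' are sorted by occupancy, descending.
#'
#' @param traj an `xl_trajectory`.
#' @param group_a,group_b [atom_selection()]s; donors of each group are
#'   paired with acceptors of the other.
#' @param dist_cutoff donor-acceptor distance cutoff, Angstrom
#'   (default 3.5).
#' @param angle_cutoff minimum D-H...A angle, degrees (default 120).
#' @return data frame: donor/acceptor atom descriptors, `occupancy`
#'   (fraction of frames), `mean_distance`, `mean_angle` (NA without
#'   hydrogens).
#' @export
hbond_census <- function(traj, group_a, group_b, dist_cutoff = 3.5,
                         angle_cutoff = 120) {
  stopifnot(inherits(traj, "xl_trajectory"))
  at <- traj$topology$atoms
  ia <- select_atoms(traj, group_a)
  ib <- select_atoms(traj, group_b)
  polar <- function(idx) idx[at$element[idx] %in% c("N", "O")]
  pa <- polar(ia); pb <- polar(ib)
  if (!length(pa) || !length(pb)) {
    return(empty_hbond_frame())
  }
  ref <- traj$frames[[1]]
  hyd <- which(at$element == "H")
  attached_h <- lapply(seq_len(nrow(at)), function(i) integer(0))
  if (length(hyd)) {
    for (d in unique(c(pa, pb))) {
      dd <- sqrt(rowSums((ref[hyd, , drop = FALSE] -
                          matrix(ref[d, ], length(hyd), 3, byrow = TRUE))^2))
      attached_h[[d]] <- hyd[dd <= 1.2]
    }
  }
  cand <- rbind(expand.grid(donor = pa, acceptor = pb),
                expand.grid(donor = pb, acceptor = pa))
  cand <- cand[at$seq_num[cand$donor] != at$seq_num[cand$acceptor] |
               at$chain_id[cand$donor] != at$chain_id[cand$acceptor], ,
               drop = FALSE]
  cand <- cand[!duplicated(paste(cand$donor, cand$acceptor)), , drop = FALSE]
  if (!nrow(cand)) return(empty_hbond_frame())

  nf <- length(traj$frames)
  hits <- matrix(FALSE, nrow(cand), nf)
  dmat <- matrix(NA_real_, nrow(cand), nf)
  amat <- matrix(NA_real_, nrow(cand), nf)
  for (f in seq_len(nf)) {
    fr <- traj$frames[[f]]
    d <- sqrt(rowSums((fr[cand$donor, , drop = FALSE] -
                       fr[cand$acceptor, , drop = FALSE])^2))
    ok <- d <= dist_cutoff
    ang <- rep(NA_real_, nrow(cand))
    for (r in which(ok)) {
      hs <- attached_h[[cand$donor[r]]]
      if (length(hs)) {
        angs <- vapply(hs, function(h) {
          v1 <- fr[cand$donor[r], ] - fr[h, ]
          v2 <- fr[cand$acceptor[r], ] - fr[h, ]
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        }, 0)
        ang[r] <- max(angs)
        if (ang[r] < angle_cutoff) ok[r] <- FALSE
      }
    }
    hits[, f] <- ok
    dmat[, f] <- ifelse(ok, d, NA)
    amat[, f] <- ifelse(ok, ang, NA)
  }
  ever <- rowSums(hits) > 0
  if (!any(ever)) return(empty_hbond_frame())
  lab <- function(idx) paste(at$chain_id[idx], at$seq_num[idx],
                             at$res_name[idx], at$atom_name[idx], sep = ":")
  out <- data.frame(
    donor = lab(cand$donor[ever]),
    acceptor = lab(cand$acceptor[ever]),
    occupancy = rowMeans(hits[ever, , drop = FALSE]),
    mean_distance = rowMeans(dmat[ever, , drop = FALSE], na.rm = TRUE),
    mean_angle = rowMeans(amat[ever, , drop = FALSE], na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  out[order(-out$occupancy, out$donor, out$acceptor), , drop = FALSE]
}

empty_hbond_frame <- function() {
  data.frame(donor = character(), acceptor = character(),
             occupancy = numeric(), mean_distance = numeric(),
             mean_angle = numeric(), stringsAsFactors = FALSE)
}
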