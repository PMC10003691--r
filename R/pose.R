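#' Rigid-body docking poses
#'
#' A pose places a ligand assembly in the receptor frame via a rigid
#' transform. Poses typically come from an external docking engine (or from
#' the synthetic generators); this package scores, filters, clusters and
#' truncates them against cross-link restraints and steric clashes.
#'
#' @param pose_id identifier string.
#' @param transform an [rigid_transform()].
#' @param provenance free-text provenance.
#' @export
xl_pose <- function(pose_id, transform, provenance = "") {
  stopifnot(is.character(pose_id), inherits(transform, "xl_transform"))
  structure(list(pose_id = pose_id, transform = transform,
                 provenance = provenance), class = "xl_pose")
}

#' Read / write pose lists
#'
#' Delimited text: one row per pose, `pose_id` then 12 transform numbers
#' (row-major rotation, then translation).
#'
#' @param path file path.
#' @export
read_pose_list <- function(path) {
  xfs <- read_transforms(path)
  mapply(function(id, xf) xl_pose(id, xf, provenance = basename(path)),
         names(xfs), xfs, SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' @param poses list of `xl_pose`.
#' @rdname read_pose_list
#' @export
write_pose_list <- function(poses, path) {
  xfs <- lapply(poses, `[[`, "transform")
  names(xfs) <- vapply(poses, `[[`, "", "pose_id")
  write_transforms(xfs, path)
}

#' Score a docking pose against cross-links and clashes
#'
#' The ligand assembly is placed by the pose transform; the combined
#' receptor + posed-ligand assembly is then evaluated: `n_satisfied` is the
#' number of cross-links whose minimum-over-copies CA-CA distance is within
#' its linker budget, and `clash_count` is the number of inter-assembly
#' CA-CA pairs closer than `clash_cutoff` between the posed ligand and the
#' core assembly (the receptor itself when no separate core is supplied).
#' A pose passes when `n_satisfied >= min_satisfied` and
#' `clash_count <= max_clash`.
#'
#' @param pose an `xl_pose`.
#' @param receptor,ligand `xl_assembly` objects. Chain labels in
#'   `chain_assignment` refer to `"R/<label>"` and `"L/<label>"` prefixes
#'   of the combined assembly; assignments given in terms of the original
#'   receptor/ligand labels are prefixed automatically via
#'   `receptor_proteins` / `ligand_proteins`.
#' @param links an `xl_crosslinks` table.
#' @param receptor_proteins,ligand_proteins character vectors naming which
#'   proteins in `links` live on the receptor and on the ligand.
#' @param core optional `xl_assembly` used for clash screening instead of
#'   the receptor (e.g. a full 24-mer core when docking onto a trimer).
#' @param offsets optional residue-number offset map (see
#'   [map_crosslinks()]).
#' @param min_satisfied restraint-count threshold (default 3).
#' @param max_clash maximum tolerated clash count (default 0).
#' @param clash_cutoff CA-CA distance below which a pair counts as one
#'   clash (default 3.0 Angstrom).
#' @param registry linker registry.
#' @return list of class `xl_pose_score`: `pose_id`, `n_satisfied`,
#'   `n_mappable`, `clash_count`, `passed`, and the underlying mapping.
#' @export
score_pose <- function(pose, receptor, ligand, links,
                       receptor_proteins, ligand_proteins,
                       core = NULL, offsets = NULL,
                       min_satisfied = 3L, max_clash = 0L,
                       clash_cutoff = 3.0, registry = default_linkers()) {
  stopifnot(inherits(pose, "xl_pose"))
  posed <- transform_assembly(ligand, pose$transform)
  combined <- combine_assemblies(receptor, posed)
  links <- if (inherits(links, "xl_crosslinks")) links else crosslink_table(links, registry)

  prots <- unique(c(links$protein_a, links$protein_b))
  unresolved <- setdiff(prots, c(receptor_proteins, ligand_proteins))
  if (length(unresolved)) {
    stop("score_pose: protein(s) not assigned to receptor or ligand: ",
         paste(unresolved, collapse = ", "))
  }
  rec_labels <- paste0("R/", unique(receptor$atoms$chain_label))
  lig_labels <- paste0("L/", unique(ligand$atoms$chain_label))
  assignment <- c(
    stats::setNames(rep(list(rec_labels), length(receptor_proteins)),
                    receptor_proteins),
    stats::setNames(rep(list(lig_labels), length(ligand_proteins)),
                    ligand_proteins)
  )

  mapping <- map_crosslinks(combined, links, assignment, offsets = offsets,
                            registry = registry)
  sat <- evaluate_satisfaction(mapping)

  clash_ref <- if (is.null(core)) receptor else core
  clash_count <- count_ca_clashes(posed, clash_ref, clash_cutoff)

  out <- list(pose_id = pose$pose_id,
              n_satisfied = sat$n_satisfied,
              n_mappable = sat$n_mappable,
              clash_count = clash_count,
              passed = sat$n_satisfied >= min_satisfied &&
                       clash_count <= max_clash,
              mapping = mapping)
  class(out) <- "xl_pose_score"
  out
}

# stack two assemblies into one, prefixing copy ids and chain labels
combine_assemblies <- function(a, b, prefixes = c("R", "L")) {
  tag <- function(x, p) {
    x$atoms$copy_id <- paste0(p, "/", x$atoms$copy_id)
    x$atoms$chain_label <- paste0(p, "/", x$atoms$chain_label)
    x
  }
  a <- tag(a, prefixes[1]); b <- tag(b, prefixes[2])
  atoms <- rbind(a$atoms, b$atoms)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, coords = rbind(a$coords, b$coords),
                 source = NULL, transforms = c(a$transforms, b$transforms)),
            class = "xl_assembly")
}

# number of inter-assembly CA-CA pairs closer than cutoff
count_ca_clashes <- function(a, b, cutoff) {
  xa <- a$coords[a$atoms$atom_name == "CA", , drop = FALSE]
  xb <- b$coords[b$atoms$atom_name == "CA", , drop = FALSE]
  if (!nrow(xa) || !nrow(xb)) return(0L)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sum(d2 < cutoff^2)
}

#' Tabulate pose scores
#' @param scores list of `xl_pose_score`.
#' @return data frame with one row per pose.
#' @export
pose_score_table <- function(scores) {
  data.frame(
    pose_id = vapply(scores, `[[`, "", "pose_id"),
    n_satisfied = vapply(scores, `[[`, 0L, "n_satisfied"),
    n_mappable = vapply(scores, `[[`, 0L, "n_mappable"),
    clash_count = vapply(scores, function(s) as.integer(s$clash_count), 0L),
    passed = vapply(scores, `[[`, TRUE, "passed"),
    stringsAsFactors = FALSE
  )
}

#' Filter poses on restraint count and clash count
#'
#' Keeps poses with at least `min_satisfied` satisfied cross-link
#' restraints and at most `max_clash` clashes, preserving input order.
#'
#' @param scores list of `xl_pose_score` or a [pose_score_table()] frame.
#' @param min_satisfied restraint threshold (default 3).
#' @param max_clash clash tolerance (default 0).
#' @return character vector of surviving pose ids, in input order.
#' @export
filter_poses <- function(scores, min_satisfied = 3L, max_clash = 0L) {
  tab <- if (is.data.frame(scores)) scores else pose_score_table(scores)
  tab$pose_id[tab$n_satisfied >= min_satisfied & tab$clash_count <= max_clash]
}

#' Truncate a pose list to the best n
#'
#' Total order: satisfied restraints descending, clashes ascending, then
#' pose id lexically — fully deterministic, so the cut is reproducible.
#'
#' @param scores list of `xl_pose_score` or a [pose_score_table()] frame.
#' @param n_keep list length to keep (default 30).
#' @return character vector of the top `n_keep` pose ids.
#' @export
truncate_pose_list <- function(scores, n_keep = 30L) {
  tab <- if (is.data.frame(scores)) scores else pose_score_table(scores)
  ord <- order(-tab$n_satisfied, tab$clash_count, tab$pose_id)
  tab$pose_id[ord][seq_len(min(n_keep, nrow(tab)))]
}

#' Pose feature matrix for clustering
#'
#' One row per pose: the posed ligand CA coordinates (or any selection of
#' them), expressed in the receptor frame and flattened. Euclidean distance
#' between rows is then a rigid-motion-meaningful dissimilarity: two poses
#' differing by a pure translation `d` are `d * sqrt(N)` apart for `N`
#' selected atoms.
#'
#' @param poses list of `xl_pose`.
#' @param ligand the ligand `xl_assembly` in its reference frame.
#' @param sel an [atom_selection()] on the ligand (default: CA atoms).
#' @return numeric matrix, poses x (3 * n selected atoms), rownames =
#'   pose ids.
#' @export
featurize_poses <- function(poses, ligand,
                            sel = atom_selection(element_class = "calpha")) {
  if (!length(poses)) stop("featurize_poses: at least one pose required")
  idx <- select_atoms_assembly(ligand, sel)
  if (!length(idx)) stop("featurize_poses: empty atom selection")
  base <- ligand$coords[idx, , drop = FALSE]
  feats <- t(vapply(poses, function(p) {
    as.vector(t(apply_transform(p$transform, base)))
  }, numeric(3 * length(idx))))
  rownames(feats) <- vapply(poses, `[[`, "", "pose_id")
  feats
}

# select_atoms for an assembly (same predicate machinery)
select_atoms_assembly <- function(a, sel) select_atoms(a, sel)

#' Ward clustering of poses
#'
#' Agglomerative hierarchical clustering under Ward's minimum-variance
#' criterion (squared-Euclidean Lance-Williams update, i.e. `hclust`'s
#' `"ward.D2"` on Euclidean distances), cut at `k` clusters. Each cluster's
#' representative is its medoid: the member minimising the summed
#' within-cluster Euclidean distance, ties broken toward the lowest row
#' index — so the representative is always a real pose.
#'
#' @param features pose feature matrix from [featurize_poses()] (or any
#'   numeric matrix, one row per item).
#' @param k number of clusters (1 <= k <= nrow).
#' @return list of class `xl_clusters`: `labels` (named integer vector),
#'   `merge`, `heights`, `k`, `representatives` (named character vector,
#'   one pose id per cluster).
#' @export
ward_cluster <- function(features, k) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (k < 1L || k > n) stop("ward_cluster: k must be between 1 and the number of rows")
  ids <- rownames(features)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n == 1L) {
    out <- list(labels = stats::setNames(1L, ids), merge = NULL,
                heights = numeric(0), k = 1L,
                representatives = stats::setNames(ids, "1"))
    class(out) <- "xl_clusters"
    return(out)
  }
  d <- stats::dist(features)
  hc <- stats::hclust(d, method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  names(labels) <- ids

  dm <- as.matrix(d)
  reps <- vapply(sort(unique(labels)), function(cl) {
    members <- which(labels == cl)
    sums <- rowSums(dm[members, members, drop = FALSE])
    ids[members[which.min(sums)]]   # which.min takes the first = lowest index
  }, "")
  names(reps) <- as.character(sort(unique(labels)))

  out <- list(labels = labels, merge = hc$merge, heights = hc$height,
              k = k, representatives = reps)
  class(out) <- "xl_clusters"
  out
}

#' @export
print.xl_clusters <- function(x, ...) {
  cat(sprintf("<xl_clusters> %d items in %d clusters; representatives: %s\n",
              length(x$labels), x$k, paste(x$representatives, collapse = " ")))
  invisible(x)
}

#' Write a pose score report
#'
#' Delimited text with per-pose restraint satisfaction, clash count, pass
#' flag and (optionally) cluster label.
#'
#' @param scores list of `xl_pose_score` or a score table.
#' @param path output path.
#' @param clusters optional `xl_clusters` whose labels are joined in.
#' @export
write_pose_report <- function(scores, path, clusters = NULL) {
  tab <- if (is.data.frame(scores)) scores else pose_score_table(scores)
  if (!is.null(clusters)) {
    tab$cluster <- unname(clusters$labels[tab$pose_id])
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
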