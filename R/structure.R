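#' Multi-chain structures
#'
#' An `xl_structure` holds one topology (an atom table) and one or more
#' models (coordinate sets sharing that topology). Multi-model PDB files are
#' the canonical trajectory interchange format. Author (PDB) residue
#' numbering is kept verbatim and is authoritative throughout the package.
#'
#' @param atoms data frame with columns `serial`, `atom_name`, `element`,
#'   `res_name`, `chain_id`, `seq_num`, `icode`, `occupancy`, `bfactor`,
#'   `is_hetero`.
#' @param coords a single n x 3 matrix or a list of them (one per model),
#'   Angstrom.
#' @param title optional title string.
#' @return An object of class `xl_structure`.
#' @export
xl_structure <- function(atoms, coords, title = "") {
  if (is.matrix(coords)) coords <- list(coords)
  if (length(coords) == 0L) stop("xl_structure: at least one model required")
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  n <- nrow(atoms)
  for (m in coords) {
    if (nrow(m) != n || ncol(m) != 3L) {
      stop("xl_structure: every model must be an n x 3 matrix matching the atom table")
    }
    if (!all(is.finite(m))) stop("xl_structure: non-finite coordinates")
  }
  req <- c("serial", "atom_name", "element", "res_name", "chain_id",
           "seq_num", "icode", "occupancy", "bfactor", "is_hetero")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("xl_structure: atom table missing columns: ",
                         paste(miss, collapse = ", "))
  key <- paste(atoms$chain_id, atoms$seq_num, atoms$icode, atoms$atom_name)
  if (anyDuplicated(key)) {
    stop("xl_structure: duplicate (chain, residue, icode, atom) entries after altloc resolution")
  }
  structure(list(atoms = atoms, coords = coords, title = title),
            class = "xl_structure")
}

#' @export
print.xl_structure <- function(x, ...) {
  cat(sprintf("<xl_structure> %d atoms, %d residue(s), %d chain(s), %d model(s)\n",
              nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain_id", "seq_num", "icode")])),
              length(unique(x$atoms$chain_id)),
              length(x$coords)))
  invisible(x)
}

#' Number of atoms / models of a structure
#' @param s an `xl_structure`.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' @rdname n_atoms
#' @export
n_models <- function(s) length(s$coords)

#' Read a PDB file
#'
#' Parses ATOM/HETATM/MODEL records through bio3d. Alternate locations are
#' resolved per `altloc_policy` (default keeps the highest-occupancy
#' conformer, ties broken toward label "A"). HETATM records (and thus
#' waters and ligands) are dropped unless `keep_hetero = TRUE` — only
#' protein geometry enters any downstream computation.
#'
#' @param path path to a PDB file (multi-model allowed).
#' @param altloc_policy `"occupancy"` (default) or `"first"`.
#' @param keep_hetero keep HETATM records? Default `FALSE`.
#' @return An `xl_structure`; models of a multi-model file become the
#'   structure's models and share one topology.
#' @export
read_structure <- function(path, altloc_policy = c("occupancy", "first"),
                           keep_hetero = FALSE) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("read_structure: file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("read_structure: unreadable PDB file: ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (!keep_hetero) {
    keep <- at$type == "ATOM"
    if (!any(keep)) stop("read_structure: no ATOM records in ", path)
  } else {
    keep <- rep(TRUE, nrow(at))
    if (!nrow(at)) stop("read_structure: no ATOM records in ", path)
  }
  idx <- which(keep)
  at <- at[idx, , drop = FALSE]

  occ <- ifelse(is.na(at$o), 1, at$o)
  alt <- ifelse(is.na(at$alt), "", at$alt)
  # altloc resolution: group atoms that differ only by altloc label
  akey <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
                at$elety)
  if (anyDuplicated(akey)) {
    ord <- if (altloc_policy == "occupancy") {
      order(akey, -occ, alt)        # highest occupancy, then label 'A'
    } else {
      order(akey, seq_len(nrow(at)))
    }
    first <- !duplicated(akey[ord])
    sel <- sort(ord[first])
    at <- at[sel, , drop = FALSE]
    occ <- occ[sel]
    idx <- idx[sel]
  }

  atoms <- data.frame(
    serial = at$eleno,
    atom_name = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     guess_element(at$elety), at$elesy),
    res_name = at$resid,
    chain_id = ifelse(is.na(at$chain), "A", at$chain),
    seq_num = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    occupancy = pmin(pmax(occ, 0), 1),
    bfactor = ifelse(is.na(at$b), 0, at$b),
    is_hetero = at$type != "ATOM",
    stringsAsFactors = FALSE
  )

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  coords <- lapply(seq_len(nrow(xyz)), function(m) {
    matrix(xyz[m, cols], ncol = 3, byrow = TRUE)
  })
  xl_structure(atoms, coords, title = basename(path))
}

# crude element guess from the atom name (first alpha character)
guess_element <- function(name) {
  e <- sub("^[0-9']*", "", name)
  e <- substr(e, 1, 1)
  toupper(e)
}

#' Write a structure as PDB
#'
#' Multi-model structures are written with MODEL/ENDMDL records. A
#' round-trip through [read_structure()] preserves topology exactly and
#' coordinates to the PDB fixed precision (1e-3 Angstrom).
#'
#' @param s an `xl_structure`.
#' @param path output path.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "xl_structure"))
  if (length(s$coords) == 0L) stop("write_structure: structure has no models")
  big <- vapply(s$coords, function(m) max(abs(m)), 0)
  if (any(big >= 10000)) {
    stop("write_structure: coordinate magnitude exceeds the PDB field width")
  }
  xyz <- do.call(rbind, lapply(s$coords, function(m) as.vector(t(m))))
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    type = ifelse(s$atoms$is_hetero, "HETATM", "ATOM"),
    resno = s$atoms$seq_num,
    resid = s$atoms$res_name,
    eleno = s$atoms$serial,
    elety = s$atoms$atom_name,
    chain = s$atoms$chain_id,
    insert = ifelse(s$atoms$icode == "", NA, s$atoms$icode),
    o = s$atoms$occupancy,
    b = s$atoms$bfactor,
    elesy = s$atoms$element
  )
  invisible(path)
}

#' Trajectories
#'
#' An `xl_trajectory` is an ordered set of frames sharing one topology.
#' [as_trajectory()] converts a (multi-model) structure; [read_trajectory()]
#' reads a multi-model PDB.
#'
#' @param topology an `xl_structure` (its first model is the reference
#'   conformation).
#' @param frames list of n x 3 coordinate matrices.
#' @param frame_interval frame spacing (arbitrary time units; metadata only).
#' @export
xl_trajectory <- function(topology, frames, frame_interval = 1) {
  stopifnot(inherits(topology, "xl_structure"))
  n <- n_atoms(topology)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (nrow(f) != n || ncol(f) != 3L) {
      stop("xl_trajectory: frame dimensions must match the topology")
    }
    f
  })
  if (length(frames) == 0L) stop("xl_trajectory: at least one frame required")
  structure(list(topology = topology, frames = frames,
                 frame_interval = frame_interval),
            class = "xl_trajectory")
}

#' @param s an `xl_structure` whose models become the frames.
#' @rdname xl_trajectory
#' @export
as_trajectory <- function(s, frame_interval = 1) {
  xl_trajectory(s, s$coords, frame_interval)
}

#' @param path multi-model PDB path.
#' @rdname xl_trajectory
#' @export
read_trajectory <- function(path, frame_interval = 1) {
  as_trajectory(read_structure(path), frame_interval)
}

#' @rdname xl_trajectory
#' @export
n_frames <- function(t) length(t$frames)

#' @export
print.xl_trajectory <- function(x, ...) {
  cat(sprintf("<xl_trajectory> %d frames x %d atoms\n",
              length(x$frames), n_atoms(x$topology)))
  invisible(x)
}

#' Write a trajectory as multi-model PDB
#' @param t an `xl_trajectory`.
#' @param path output path.
#' @export
write_trajectory <- function(t, path) {
  write_structure(xl_structure(t$topology$atoms, t$frames,
                               title = t$topology$title), path)
}
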