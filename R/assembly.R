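#' Homo-oligomeric assemblies
#'
#' An assembly replicates a source structure under a list of rigid
#' transforms — e.g. a protomer assembled into a dimer or trimer. Each copy
#' keeps the source's author residue numbering; chains are relabelled with
#' unique synthetic labels `"<copy_id>/<chain_id>"` so that copies can be
#' distinguished when resolving cross-link ambiguity.
#'
#' @param s source `xl_structure` (its first model is replicated).
#' @param transforms list of [rigid_transform()] placements, one per copy.
#' @param copy_ids optional character vector of copy names (default
#'   `"c1"`, `"c2"`, ...).
#' @return An object of class `xl_assembly` with fields `atoms` (atom table
#'   with `copy_id`, `chain_label` and `source_chain` columns), `coords`
#'   (n x 3), `source` and `transforms`.
#' @export
build_assembly <- function(s, transforms, copy_ids = NULL) {
  stopifnot(inherits(s, "xl_structure"))
  if (inherits(transforms, "xl_transform")) transforms <- list(transforms)
  k <- length(transforms)
  if (k < 1L) stop("build_assembly: at least one transform required")
  for (xf in transforms) {
    if (!inherits(xf, "xl_transform")) {
      stop("build_assembly: transforms must be xl_transform objects")
    }
    # re-validate: objects may have been constructed or edited by hand
    rigid_transform(xf$R, xf$t)
  }
  if (is.null(copy_ids)) copy_ids <- paste0("c", seq_len(k))
  stopifnot(length(copy_ids) == k, !anyDuplicated(copy_ids))
  names(transforms) <- copy_ids

  base <- s$atoms
  per <- lapply(seq_len(k), function(i) {
    a <- base
    a$copy_id <- copy_ids[i]
    a$source_chain <- a$chain_id
    a$chain_label <- paste0(copy_ids[i], "/", a$chain_id)
    a
  })
  atoms <- do.call(rbind, per)
  coords <- do.call(rbind, lapply(transforms, function(xf) {
    apply_transform(xf, s$coords[[1]])
  }))
  rownames(atoms) <- NULL
  dimnames(coords) <- NULL
  structure(list(atoms = atoms, coords = coords, source = s,
                 transforms = transforms),
            class = "xl_assembly")
}

#' Treat a structure as a single-copy assembly
#' @param s an `xl_structure`.
#' @param copy_id copy name.
#' @export
as_assembly <- function(s, copy_id = "c1") {
  build_assembly(s, list(identity_transform()), copy_ids = copy_id)
}

#' @export
print.xl_assembly <- function(x, ...) {
  cat(sprintf("<xl_assembly> %d copies, %d atoms, chains: %s\n",
              length(x$transforms), nrow(x$atoms),
              paste(unique(x$atoms$chain_label), collapse = " ")))
  invisible(x)
}

#' Apply a rigid transform to a whole assembly
#' @param a an `xl_assembly`.
#' @param xf an `xl_transform`.
#' @export
transform_assembly <- function(a, xf) {
  a$coords <- apply_transform(xf, a$coords)
  a$transforms <- lapply(a$transforms, function(old) compose_transforms(xf, old))
  a
}

#' Atom selections
#'
#' A declarative predicate over chain labels, residue ranges, atom names
#' and element class. `element_class = "calpha"` selects CA atoms,
#' `"backbone"` selects N/CA/C/O, `"heavy"` excludes hydrogens.
#'
#' @param chains character vector of chain labels (assembly `chain_label`
#'   or structure `chain_id`), or `NULL` for all.
#' @param resno integer vector of residue numbers (author numbering), or
#'   `NULL` for all.
#' @param atom_names character vector of atom names, or `NULL`.
#' @param element_class one of `"all"`, `"heavy"`, `"calpha"`, `"backbone"`.
#' @export
atom_selection <- function(chains = NULL, resno = NULL, atom_names = NULL,
                           element_class = c("all", "heavy", "calpha", "backbone")) {
  element_class <- match.arg(element_class)
  structure(list(chains = chains, resno = resno, atom_names = atom_names,
                 element_class = element_class),
            class = "xl_selection")
}

#' Select atoms from an assembly, structure or trajectory topology
#'
#' Returns integer atom indices in a deterministic order: copy, chain,
#' residue number, insertion code, atom name. Selecting nothing returns an
#' empty vector (no error).
#'
#' @param x an `xl_assembly`, `xl_structure` or `xl_trajectory`.
#' @param sel an [atom_selection()].
#' @return integer vector of atom indices into `x`'s atom table.
#' @export
select_atoms <- function(x, sel = atom_selection()) {
  if (inherits(x, "xl_trajectory")) x <- x$topology
  if (!inherits(sel, "xl_selection")) stop("select_atoms: sel must be an atom_selection")
  at <- x$atoms
  chain_col <- if (!is.null(at$chain_label)) at$chain_label else at$chain_id
  keep <- rep(TRUE, nrow(at))
  if (!is.null(sel$chains)) keep <- keep & chain_col %in% sel$chains
  if (!is.null(sel$resno)) keep <- keep & at$seq_num %in% sel$resno
  if (!is.null(sel$atom_names)) keep <- keep & at$atom_name %in% sel$atom_names
  keep <- keep & switch(sel$element_class,
    all = TRUE,
    heavy = at$element != "H",
    calpha = at$atom_name == "CA",
    backbone = at$atom_name %in% c("N", "CA", "C", "O")
  )
  idx <- which(keep)
  copy_col <- if (!is.null(at$copy_id)) at$copy_id[idx] else rep("", length(idx))
  idx[order(copy_col, chain_col[idx], at$seq_num[idx],
            at$icode[idx], at$atom_name[idx])]
}

#' Coordinates of an assembly / structure model / trajectory frame
#'
#' @param x an `xl_assembly`, `xl_structure`, or `xl_trajectory`.
#' @param model model or frame index (ignored for assemblies).
#' @export
coords_of <- function(x, model = 1L) {
  if (inherits(x, "xl_assembly")) return(x$coords)
  if (inherits(x, "xl_trajectory")) return(x$frames[[model]])
  x$coords[[model]]
}

#' Flatten an assembly into a structure
#'
#' Chain labels are remapped to single PDB characters (A-Z, a-z, 0-9) so
#' the result can be written as PDB; the mapping is returned as the
#' `chain_map` attribute.
#'
#' @param a an `xl_assembly`.
#' @export
assembly_to_structure <- function(a) {
  labs <- unique(a$atoms$chain_label)
  pool <- c(LETTERS, letters, as.character(0:9))
  if (length(labs) > length(pool)) {
    stop("assembly_to_structure: more chains than available PDB chain letters")
  }
  map <- stats::setNames(pool[seq_along(labs)], labs)
  atoms <- a$atoms
  atoms$chain_id <- unname(map[atoms$chain_label])
  atoms$serial <- seq_len(nrow(atoms))
  atoms <- atoms[, c("serial", "atom_name", "element", "res_name", "chain_id",
                     "seq_num", "icode", "occupancy", "bfactor", "is_hetero")]
  s <- xl_structure(atoms, a$coords, title = "assembly")
  attr(s, "chain_map") <- map
  s
}

#' Read / write assembly transform files
#'
#' Delimited text, one row per copy: `copy_id` then 12 numbers (row-major
#' 3x3 rotation followed by the translation, Angstrom).
#'
#' @param path file path.
#' @export
read_transforms <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) != 13L) {
    stop("read_transforms: expected copy_id + 12 numbers per row")
  }
  xfs <- lapply(seq_len(nrow(tab)), function(i) {
    transform_from_row(as.numeric(tab[i, -1]))
  })
  names(xfs) <- as.character(tab[[1]])
  xfs
}

#' @param transforms named list of `xl_transform`s.
#' @rdname read_transforms
#' @export
write_transforms <- function(transforms, path) {
  rows <- t(vapply(transforms, transform_to_row, numeric(12)))
  tab <- data.frame(copy_id = names(transforms), rows)
  names(tab) <- c("copy_id", paste0("r", 1:9), paste0("t", 1:3))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
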