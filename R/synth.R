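# Seeded generators of toy assemblies, planted docking poses with
# geometrically consistent cross-link sets, and noise trajectories. These
# are first-class, tested pipeline substrates: every generator is a pure
# function of its arguments and seed, so fixtures are bit-reproducible.

#' Build a toy multi-chain assembly
#'
#' Generates a poly-alanine-like chain with minimal backbone atoms
#' (N, CA, C, O) and replicates it into `n_chains` copies spaced
#' `chain_spacing` Angstrom apart. Every 10th residue is a Lys-like anchor
#' (residue name LYS) usable as a cross-linking site, so anchor counts are
#' closed-form. Geometries:
#'
#' * `"extended"` — CA atoms on a straight line, 3.8 A apart;
#' * `"helix"` — alpha-helical CA trace (radius 2.3 A, rise 1.5 A/residue,
#'   100 degrees/residue) folded into a compact layered meander, like
#'   antiparallel helices packed into a small domain;
#' * `"bead-spring"` — CA-only random walk with 3.8 A steps and bounded
#'   turning angle (seeded).
#'
#' @param chain_length residues per chain (>= 5).
#' @param n_chains number of copies (>= 1).
#' @param geometry `"helix"` (default), `"extended"` or `"bead-spring"`.
#' @param symmetry how copies are arranged: `"cyclic"` (default) places
#'   copy k by rotating the chain `2*pi*k/n_chains` about the z axis after
#'   an initial `chain_spacing` offset along x — the C_n arrangement of a
#'   real homo-oligomer; `"linear"` translates copies along y by
#'   `chain_spacing` each.
#' @param chain_spacing radial offset (cyclic) or inter-copy translation
#'   (linear), Angstrom.
#' @param anchor_period anchor (LYS) residue period (default 10).
#' @param leg_length straight-leg length of the meandering helix fold,
#'   Angstrom (default 45); vary it to generate non-congruent toy domains.
#' @param seed RNG seed (only the bead-spring geometry consumes it).
#' @return an `xl_assembly` of `n_chains` copies.
#' @export
make_toy_assembly <- function(chain_length, n_chains = 1L,
                              geometry = c("helix", "extended", "bead-spring"),
                              symmetry = c("cyclic", "linear"),
                              chain_spacing = 10, anchor_period = 10L,
                              leg_length = 45, seed = 1L) {
  geometry <- match.arg(geometry)
  symmetry <- match.arg(symmetry)
  if (chain_length < 5L) stop("make_toy_assembly: chain_length must be >= 5")
  s <- toy_chain(chain_length, geometry, anchor_period, seed,
                 leg_length = leg_length)
  xfs <- if (symmetry == "cyclic") {
    lapply(seq_len(n_chains) - 1L, function(k) {
      compose_transforms(rotation_transform(c(0, 0, 1),
                                            2 * pi * k / n_chains),
                         translation_transform(c(chain_spacing, 0, 0)))
    })
  } else {
    lapply(seq_len(n_chains) - 1L, function(k) {
      translation_transform(c(0, k * chain_spacing, 0))
    })
  }
  build_assembly(s, xfs)
}

#' @param chain_id chain identifier of the generated chain.
#' @rdname make_toy_assembly
#' @export
toy_chain <- function(chain_length, geometry = "helix",
                      anchor_period = 10L, seed = 1L, chain_id = "A",
                      leg_length = 45) {
  ca <- switch(geometry,
    extended = cbind(3.8 * (seq_len(chain_length) - 1L), 0, 0),
    helix = {
      # alpha-helical trace (radius 2.3 A, rise 1.5 A/res along the axis,
      # 100 deg/res) wound on a meandering axis: straight legs of length
      # `leg_length` joined by semicircular U-turns that step the path up
      # in z, like antiparallel helices packed in layers. The fold is a
      # compact 3-D domain with no screw or shift symmetry: spatially
      # close residue pairs span many different sequence offsets, so a
      # planted set of distance restraints is orientation-specific, as for
      # a real globular protein. `leg_length` varies the fold so receptor
      # and ligand toys need not be congruent.
      i <- seq_len(chain_length) - 1L
      meander_helix(1.5 * i, leg_length)
    },
    `bead-spring` = {
      old <- local_seed(seed)
      on.exit(restore_seed(old))
      x <- matrix(0, chain_length, 3)
      dir <- c(1, 0, 0)
      for (i in 2:chain_length) {
        perturb <- stats::rnorm(3, sd = 0.35)
        dir <- dir + perturb
        dir <- dir / sqrt(sum(dir^2))
        x[i, ] <- x[i - 1, ] + 3.8 * dir
      }
      x
    },
    stop("toy_chain: unknown geometry")
  )
  backbone_only <- geometry == "bead-spring"
  resno <- seq_len(chain_length)
  res_name <- ifelse(resno %% anchor_period == 0L, "LYS", "ALA")
  if (backbone_only) {
    atoms <- data.frame(
      serial = seq_len(chain_length), atom_name = "CA", element = "C",
      res_name = res_name, chain_id = chain_id, seq_num = resno, icode = "",
      occupancy = 1, bfactor = 0, is_hetero = FALSE, stringsAsFactors = FALSE)
    return(xl_structure(atoms, ca, title = "toy chain"))
  }
  # minimal backbone: fixed local offsets from each CA
  offs <- list(N = c(-1.0, 0.9, 0.3), CA = c(0, 0, 0),
               C = c(1.0, 0.9, -0.3), O = c(1.3, 2.05, -0.3))
  nm <- names(offs)
  rows <- lapply(seq_len(chain_length), function(i) {
    data.frame(serial = 0L, atom_name = nm,
               element = substr(nm, 1, 1),
               res_name = res_name[i], chain_id = chain_id, seq_num = resno[i],
               icode = "", occupancy = 1, bfactor = 0, is_hetero = FALSE,
               stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  coords <- do.call(rbind, lapply(seq_len(chain_length), function(i) {
    t(vapply(offs, function(o) ca[i, ] + o, numeric(3)))
  }))
  xl_structure(atoms, coords, title = "toy chain")
}

# CA positions of an alpha-helical trace along a meandering (boustrophedon)
# axis: straight legs along +/-x, semicircular turns (radius 10 A) stepping
# +20 A in z per turn, the whole path in the y = 0 plane; the helix winds
# around it with radius 2.3 A at 100 deg/residue.
meander_helix <- function(s, leg_length = 45, turn_radius = 10,
                          helix_radius = 2.3) {
  period <- leg_length + pi * turn_radius
  k <- floor(s / period)
  u <- s - k * period
  even <- k %% 2 == 0
  zbase <- k * 2 * turn_radius
  straight <- u <= leg_length
  alpha <- pmax(0, (u - leg_length) / turn_radius)   # turn angle in [0, pi]
  x <- ifelse(straight,
              ifelse(even, u, leg_length - u),
              ifelse(even, leg_length + turn_radius * sin(alpha),
                     -turn_radius * sin(alpha)))
  z <- ifelse(straight, zbase,
              zbase + turn_radius * (1 - cos(alpha)))
  tx <- ifelse(straight, ifelse(even, 1, -1),
               ifelse(even, cos(alpha), -cos(alpha)))
  tz <- ifelse(straight, 0, sin(alpha))
  axis <- cbind(x, 0, z)
  # local frame: u = unit vector in the x-z plane normal to the tangent,
  # v = global y; the tangent never leaves the x-z plane
  nrm <- cbind(-tz, 0, tx)
  bin <- matrix(rep(c(0, 1, 0), length(s)), ncol = 3, byrow = TRUE)
  th <- seq_along(s) * 100 * pi / 180
  axis + helix_radius * (cos(th) * nrm + sin(th) * bin)
}

# greedy random matching with a spatial-spread requirement: rows get
# pairwise-distinct res_a and res_b whose anchor CA positions (in each
# assembly's own chain frame) are pairwise at least `spread` apart. Random
# restarts make the greedy search robust.
sample_matching <- function(pairs, n, coords_a, coords_b, spread = 0,
                            retries = 2000L) {
  for (r in seq_len(retries)) {
    ord <- sample(nrow(pairs))
    used_a <- integer(0); used_b <- integer(0); take <- integer(0)
    for (i in ord) {
      ra <- pairs$res_a[i]; rb <- pairs$res_b[i]
      if (ra %in% used_a || rb %in% used_b) next
      if (spread > 0 && length(take)) {
        da <- sqrt(colSums((t(coords_a[as.character(used_a), , drop = FALSE]) -
                            coords_a[as.character(ra), ])^2))
        db <- sqrt(colSums((t(coords_b[as.character(used_b), , drop = FALSE]) -
                            coords_b[as.character(rb), ])^2))
        if (min(da) < spread || min(db) < spread) next
      }
      take <- c(take, i)
      used_a <- c(used_a, ra)
      used_b <- c(used_b, rb)
      if (length(take) == n) return(pairs[take, , drop = FALSE])
    }
  }
  NULL
}

# save/restore the global RNG state so generators are pure in (args, seed)
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Plant a pose with a geometrically consistent cross-link set
#'
#' Places the ligand with `transform`, enumerates all anchor (LYS) CA
#' pairs between receptor and posed ligand, and samples `n_true` links
#' from pairs within the linker's distance budget plus `n_false` links
#' from pairs beyond budget + 10 A (clear violations, emulating false
#' positive identifications). Protein names default to `"REC"`/`"LIG"`.
#'
#' @param receptor,ligand `xl_assembly` objects with LYS anchor residues.
#' @param transform the planted `xl_transform`.
#' @param linker linker name or `xl_linker` (default `"DSBU"`).
#' @param n_true,n_false numbers of consistent and violating links.
#' @param seed RNG seed.
#' @param proteins length-2 character: protein names for receptor and
#'   ligand rows of the table.
#' @param anchor_spread minimum pairwise CA separation (Angstrom, in each
#'   assembly's own frame) among the sampled true-link anchors on each
#'   side (default 30) — the sampled set spans the interface rather than
#'   one contact patch, as real identification sets do.
#' @param registry linker registry.
#' @return list with `pose` (an `xl_pose`), `links` (an `xl_crosslinks`
#'   table; attribute `truth` marks each row `"true"` / `"false"`).
#' @export
plant_pose_and_links <- function(receptor, ligand, transform,
                                 linker = "DSBU", n_true = 5L, n_false = 2L,
                                 seed = 1L, proteins = c("REC", "LIG"),
                                 anchor_spread = 30,
                                 registry = default_linkers()) {
  budget <- distance_budget(linker, registry)
  linker_name <- if (inherits(linker, "xl_linker")) linker$name else linker
  posed <- transform_assembly(ligand, transform)

  anch <- function(a) {
    i <- which(a$atoms$res_name == "LYS" & a$atoms$atom_name == "CA")
    list(idx = i, res = a$atoms$seq_num[i], coords = a$coords[i, , drop = FALSE])
  }
  ra <- anch(receptor); la <- anch(posed)
  if (!length(ra$idx) || !length(la$idx)) {
    stop("plant_pose_and_links: no anchor residues on one side")
  }
  d <- sqrt(pmax(outer(rowSums(ra$coords^2), rowSums(la$coords^2), "+") -
                   2 * ra$coords %*% t(la$coords), 0))
  # a link only records residue numbers; with multiple copies it is later
  # evaluated by its minimum over copy pairs, so classify residue pairs by
  # that minimum, not by individual copy-pair distances
  key <- expand.grid(res_a = unique(ra$res), res_b = unique(la$res))
  key$min_d <- mapply(function(qa, qb) {
    min(d[ra$res == qa, la$res == qb])
  }, key$res_a, key$res_b)
  under <- key[key$min_d <= budget, , drop = FALSE]
  over <- key[key$min_d > budget + 10, , drop = FALSE]
  if (nrow(under) < n_true) {
    stop("plant_pose_and_links: only ", nrow(under),
         " anchor pairs under budget at the planted pose; need ", n_true)
  }
  if (nrow(over) < n_false) {
    stop("plant_pose_and_links: only ", nrow(over),
         " anchor pairs beyond budget + 10 A; need ", n_false)
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  # true links are sampled as a spatially spread matching: distinct anchors
  # on both sides, pairwise at least `anchor_spread` apart, as in a real
  # identification set spanning an interface. Links sharing an anchor, or
  # crowded into one contact patch, collapse into a single effective
  # spatial restraint and carry far less orientation information.
  coord_of <- function(a, side) {
    i <- which(a$atoms$res_name == "LYS" & a$atoms$atom_name == "CA" &
               a$atoms$copy_id == a$atoms$copy_id[1])
    m <- a$coords[i, , drop = FALSE]
    rownames(m) <- as.character(a$atoms$seq_num[i])
    m
  }
  pick_true <- sample_matching(under, n_true,
                               coords_a = coord_of(receptor),
                               coords_b = coord_of(ligand),
                               spread = anchor_spread)
  if (is.null(pick_true)) {
    stop("plant_pose_and_links: cannot find ", n_true,
         " under-budget anchor pairs with distinct, spread-out residues ",
         "(", nrow(under), " pairs under budget; try a lower anchor_spread)")
  }
  pick_false <- over[sample(nrow(over), n_false), , drop = FALSE]
  tab <- data.frame(
    protein_a = proteins[1],
    res_a = c(pick_true$res_a, pick_false$res_a),
    protein_b = proteins[2],
    res_b = c(pick_true$res_b, pick_false$res_b),
    linker = linker_name,
    score = NA_real_,
    stringsAsFactors = FALSE
  )
  links <- crosslink_table(tab, registry)
  attr(links, "truth") <- rep(c("true", "false"), c(n_true, n_false))
  list(pose = xl_pose("planted", transform, provenance = "planted fixture"),
       links = links)
}

#' Generate random decoy poses
#'
#' Uniform random rotations (quaternion sampling) combined with
#' translations displaced at least `min_displacement` Angstrom from the
#' reference pose's translation, along uniform random directions with
#' magnitudes uniform in `[min_displacement, 2 * min_displacement]`.
#'
#' @param n number of decoys.
#' @param reference_pose pose whose translation displacements are measured
#'   from (default: origin / identity).
#' @param min_displacement minimum translation displacement, Angstrom
#'   (default 50).
#' @param seed RNG seed.
#' @return list of `xl_pose` with ids `decoy001`, `decoy002`, ...
#' @export
generate_decoy_poses <- function(n, reference_pose = NULL,
                                 min_displacement = 50, seed = 1L) {
  if (n < 1L) stop("generate_decoy_poses: n must be >= 1")
  ref_t <- if (is.null(reference_pose)) c(0, 0, 0) else
    reference_pose$transform$t
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  lapply(seq_len(n), function(i) {
    R <- random_rotation()
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    mag <- stats::runif(1, min_displacement, 2 * min_displacement)
    xl_pose(sprintf("decoy%03d", i), rigid_transform(R, ref_t + mag * u),
            provenance = sprintf("decoy seed=%d", seed))
  })
}

#' Simulate a Gaussian noise trajectory
#'
#' Frame f = equilibrium + iid per-axis Gaussian noise scaled by the
#' per-atom `sigma` profile. With isotropic per-axis sigma, the expected
#' per-atom RMSF is `sigma * sqrt(3)` — a closed form used for parameter
#' recovery checks. Optionally each frame also receives a global rigid
#' wobble (random small rotation + translation) to exercise superposition.
#'
#' @param s equilibrium `xl_structure` (first model used).
#' @param sigma per-axis noise s.d., Angstrom; scalar or per-atom vector.
#' @param n_frames number of frames (>= 2).
#' @param seed RNG seed.
#' @param wobble add a random global rigid motion per frame?
#' @return an `xl_trajectory`.
#' @export
simulate_noise_trajectory <- function(s, sigma, n_frames, seed = 1L,
                                      wobble = FALSE) {
  stopifnot(inherits(s, "xl_structure"))
  if (n_frames < 2L) stop("simulate_noise_trajectory: n_frames must be >= 2")
  n <- n_atoms(s)
  sigma <- rep_len(as.numeric(sigma), n)
  if (any(sigma < 0)) stop("simulate_noise_trajectory: sigma must be >= 0")
  eq <- s$coords[[1]]
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  frames <- lapply(seq_len(n_frames), function(f) {
    fr <- eq + matrix(stats::rnorm(3 * n), n, 3) * sigma
    if (wobble) {
      ax <- stats::rnorm(3)
      xf <- rotation_transform(ax, stats::runif(1, 0, 0.3),
                               t = stats::rnorm(3, sd = 5))
      fr <- apply_transform(xf, fr)
    }
    fr
  })
  xl_trajectory(s, frames)
}
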