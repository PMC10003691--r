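test_that("Kabsch superposition is exact on rigid motions and matches the quaternion oracle", {
  set.seed(31)
  ref <- matrix(rnorm(60), 20, 3)
  xf <- rotation_transform(c(0, 0, 1), pi / 2, t = c(5, 0, 0))
  fit <- superpose(apply_transform(xf, ref), ref)
  expect_lt(fit$rmsd, 1e-9)

  same <- superpose(ref, ref)
  expect_equal(same$transform$R, diag(3), tolerance = 1e-9)
  expect_equal(same$transform$t, c(0, 0, 0), tolerance = 1e-9)
  expect_lt(same$rmsd, 1e-12)

  for (i in 1:100) {
    a <- matrix(rnorm(60), 20, 3)
    b <- matrix(rnorm(60), 20, 3)
    expect_equal(superpose(a, b)$rmsd, quaternion_rmsd(a, b),
                 tolerance = 1e-8)
  }

  expect_error(superpose(ref[1:2, ], ref[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line + rnorm(15, sd = 1e-14), line), "collinear")
})

test_that("rmsd_series removes rigid motion and matches the quaternion route", {
  s <- toy_chain(30, "helix")
  static <- xl_trajectory(s, rep(list(s$coords[[1]]), 5))
  expect_equal(rmsd_series(static), rep(0, 5), tolerance = 1e-12)

  xf <- rotation_transform(c(1, 1, 0), 0.7, t = c(3, -2, 9))
  rigid <- xl_trajectory(s, list(s$coords[[1]],
                                 apply_transform(xf, s$coords[[1]])))
  expect_lt(max(rmsd_series(rigid)), 1e-9)

  # one atom nudged 1 A: fitted RMSD is bounded by sqrt(1/N) and equals
  # the independent quaternion value
  idx <- select_atoms(s, atom_selection(element_class = "calpha"))
  f2 <- s$coords[[1]]
  f2[idx[5], 1] <- f2[idx[5], 1] + 1
  tr <- xl_trajectory(s, list(s$coords[[1]], f2))
  got <- rmsd_series(tr)
  expect_equal(got[1], 0, tolerance = 1e-12)
  expect_lte(got[2], sqrt(1 / length(idx)) + 1e-12)
  expect_equal(got[2],
               quaternion_rmsd(f2[idx, ], s$coords[[1]][idx, ]),
               tolerance = 1e-8)
  expect_error(rmsd_series(tr, sel = atom_selection(chains = "zz")),
               "no atoms")
})

test_that("RMSF recovers the noise amplitude: sigma * sqrt(3), linear in sigma", {
  s <- toy_chain(100, "helix")
  tr0 <- simulate_noise_trajectory(s, 0, 3, seed = 1)
  expect_equal(unname(rmsf(tr0)), rep(0, 100), tolerance = 1e-12)

  tr <- simulate_noise_trajectory(s, 0.5, 2000, seed = 12)
  r <- rmsf(tr)
  expect_length(r, 100)
  expect_true(all(abs(r - 0.5 * sqrt(3)) / (0.5 * sqrt(3)) < 0.05))

  tr2 <- simulate_noise_trajectory(s, 1.0, 2000, seed = 12)
  ratio <- mean(rmsf(tr2)) / mean(r)
  expect_equal(ratio, 2, tolerance = 0.05)

  expect_error(rmsf(xl_trajectory(s, list(s$coords[[1]]))), "2 frames")
})

test_that("native contacts match the exhaustive oracle and obey the separation rule", {
  # two residues 100 A apart: no contact
  far <- ca_structure(rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_equal(nrow(native_contacts(far)), 0)

  # sequence neighbours are never contacts at min_seq_sep 3
  consec <- ca_structure(cbind(3.8 * (0:4), 0, 0))
  ct <- native_contacts(consec)
  expect_equal(nrow(ct), 0)
  ct1 <- native_contacts(consec, min_seq_sep = 1L)
  expect_true(all(abs(ct1$res_i - ct1$res_j) >= 1))

  # toy helix bundle: exact agreement with the all-pairs oracle
  s <- toy_chain(24, "helix")
  got <- native_contacts(s)
  want <- contacts_oracle(s, s$coords[[1]])
  expect_equal(nrow(got), nrow(want))
  if (nrow(got)) {
    expect_equal(got$distance, unname(want[, 3]), tolerance = 1e-9)
  }

  # inter/intra scopes partition the both-scope set
  a <- make_toy_assembly(20, n_chains = 2, symmetry = "linear", chain_spacing = 4)
  s2 <- assembly_to_structure(a)
  n_both <- nrow(native_contacts(s2, scope = "both"))
  n_intra <- nrow(native_contacts(s2, scope = "intra"))
  n_inter <- nrow(native_contacts(s2, scope = "inter"))
  expect_equal(n_both, n_intra + n_inter)
  expect_gt(n_inter, 0)
})

test_that("Q starts at 1, lives in [0,1], and counts broken contacts exactly", {
  s <- ten_contact_structure()
  ct <- native_contacts(s)
  expect_equal(nrow(ct), 10)

  f1 <- s$coords[[1]]
  exploded <- f1 * 10
  broken2 <- f1
  broken2[21:22, 3] <- broken2[21:22, 3] + 50   # partners of residues 9, 10
  tr <- xl_trajectory(s, list(f1, exploded, broken2))
  q <- q_series(tr, ct)
  expect_equal(q[1], 1)
  expect_equal(q[2], 0)
  expect_equal(q[3], 0.8)
  expect_true(all(q >= 0 & q <= 1))
  expect_error(q_series(tr, native_contacts(ca_structure(rbind(c(0,0,0), c(99,0,0))))),
               "empty")
})

test_that("contact maps report per-pair frame frequencies", {
  a <- make_toy_assembly(10, n_chains = 2, symmetry = "linear", chain_spacing = 200)
  s <- assembly_to_structure(a)
  tr <- xl_trajectory(s, list(s$coords[[1]], s$coords[[1]]))
  selA <- atom_selection(chains = "A")
  selB <- atom_selection(chains = "B")
  m_far <- contact_map(tr, selA, selB)
  expect_true(all(m_far == 0))

  a2 <- make_toy_assembly(10, n_chains = 2, symmetry = "linear", chain_spacing = 4)
  s2 <- assembly_to_structure(a2)
  f1 <- s2$coords[[1]]
  f2 <- f1
  f2[s2$atoms$chain_id == "B", 2] <- f2[s2$atoms$chain_id == "B", 2] + 300
  tr2 <- xl_trajectory(s2, list(f1, f1))
  m_static <- contact_map(tr2, selA, selB)
  expect_true(all(m_static %in% c(0, 1)))
  expect_gt(sum(m_static), 0)

  tr3 <- xl_trajectory(s2, list(f1, f2))
  m_half <- contact_map(tr3, selA, selB)
  expect_true(all(m_half %in% c(0, 0.5)))
  expect_equal(m_half[m_half > 0], m_static[m_static > 0] / 2,
               ignore_attr = TRUE)
  expect_error(contact_map(tr3, atom_selection(chains = "zz"), selB), "empty")
})

test_that("hydrogen-bond census applies distance+angle criteria and occupancy", {
  mk <- function(o_x) {
    atoms <- data.frame(
      serial = 1:3,
      atom_name = c("N", "H", "O"),
      element = c("N", "H", "O"),
      res_name = "ALA",
      chain_id = c("A", "A", "B"),
      seq_num = c(1L, 1L, 1L),
      icode = "", occupancy = 1, bfactor = 0, is_hetero = FALSE,
      stringsAsFactors = FALSE)
    coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(o_x, 0, 0))
    xl_structure(atoms, coords)
  }
  s <- mk(2.9)
  selA <- atom_selection(chains = "A")
  selB <- atom_selection(chains = "B")
  tr <- xl_trajectory(s, rep(list(s$coords[[1]]), 4))
  hb <- hbond_census(tr, selA, selB)
  rec <- hb[grepl(":N$", hb$donor), ]
  expect_equal(nrow(rec), 1)
  expect_equal(rec$occupancy, 1.0)
  expect_equal(rec$mean_distance, 2.9, tolerance = 1e-9)
  expect_equal(rec$mean_angle, 180, tolerance = 1e-6)

  s_far <- mk(5.0)
  tr_far <- xl_trajectory(s_far, rep(list(s_far$coords[[1]]), 4))
  expect_equal(nrow(hbond_census(tr_far, selA, selB)), 0)

  # satisfied in 1 of 4 frames -> occupancy 0.25
  near <- s$coords[[1]]
  away <- near; away[3, 1] <- 50
  tr_mix <- xl_trajectory(s, list(near, away, away, away))
  hb_mix <- hbond_census(tr_mix, selA, selB)
  expect_equal(unique(hb_mix$occupancy), 0.25)

  # a bent geometry (angle < 120 deg) fails despite a short distance
  bent <- s
  bent$coords[[1]][2, ] <- c(0, 1, 0)    # H perpendicular to N...O axis
  tr_bent <- as_trajectory(bent)
  hb_bent <- hbond_census(tr_bent, selA, selB)
  expect_false(any(grepl(":N$", hb_bent$donor)))
})

test_that("ANM spectra: rigid-body null space, orthonormality, oracle agreement", {
  tet <- ca_structure(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                            c(0.5, sqrt(3) / 6, sqrt(2 / 3))) * 10)
  m <- anm_modes(tet, cutoff = 15)
  expect_equal(m$n_zero, 6)
  expect_equal(sum(m$values > 1e-8 * max(m$values)), 6)
  G <- crossprod(m$vectors)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-8)

  # a genuinely 3-D 10-node curve (near-collinear chains would blur the
  # rigid-body / bending eigenvalue gap)
  th <- (0:9) * 100 * pi / 180
  chain <- ca_structure(cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * (0:9)))
  m10 <- anm_modes(chain, cutoff = 8)
  oracle <- anm_oracle_spectrum(chain$coords[[1]], cutoff = 8)
  expect_equal(m10$values, pmax(oracle, 0), tolerance = 1e-8)
  expect_equal(m10$n_zero, 6)

  # isolated node -> honest warning and extra zero modes
  disc <- ca_structure(rbind(cbind(3.8 * (0:3), 0, 0), c(500, 0, 0)))
  expect_warning(md <- anm_modes(disc, cutoff = 8), "disconnected")
  expect_gt(md$n_zero, 6)
})

test_that("mode animation has the sine symmetry and closed-form amplitude", {
  s <- toy_chain(20, "helix")
  m <- anm_modes(s, cutoff = 12)
  k <- nontrivial_mode(m, 1)

  tr0 <- mode_trajectory(m, k, amplitude = 0, n_frames = 8)
  for (f in tr0$frames) expect_equal(f, m$ca_coords, tolerance = 1e-12)

  A <- 2.5
  tr <- mode_trajectory(m, k, amplitude = A, n_frames = 16)
  disp <- vapply(tr$frames, function(f) {
    max(sqrt(rowSums((f - m$ca_coords)^2)))
  }, 0)
  vec <- matrix(m$vectors[, k], ncol = 3, byrow = TRUE)
  expect_equal(max(disp), A * max(sqrt(rowSums(vec^2))), tolerance = 1e-6)

  # frames k and n-k mirror about the equilibrium
  n <- length(tr$frames)
  for (j in 2:(n / 2)) {
    dev_a <- tr$frames[[j]] - m$ca_coords
    dev_b <- tr$frames[[n - j + 2]] - m$ca_coords
    expect_equal(dev_a, -dev_b, tolerance = 1e-9)
  }
  expect_error(mode_trajectory(m, 3, 1), "rigid-body")
})

test_that("trajectory PCA matches the covariance oracle and conserves variance", {
  s <- toy_chain(15, "helix")
  idx <- select_atoms(s, atom_selection(element_class = "calpha"))

  # motion along one fixed internal vector -> first component explains
  # everything. The vector must be orthogonal to the 6 rigid-body modes of
  # the reference, otherwise the per-frame superposition absorbs part of it.
  set.seed(77)
  ref_ca <- s$coords[[1]][idx, , drop = FALSE]
  cen <- sweep(ref_ca, 2, colMeans(ref_ca))
  rigid <- cbind(
    rep(c(1, 0, 0), length(idx)), rep(c(0, 1, 0), length(idx)),
    rep(c(0, 0, 1), length(idx)),
    as.vector(t(cbind(0, -cen[, 3], cen[, 2]))),
    as.vector(t(cbind(cen[, 3], 0, -cen[, 1]))),
    as.vector(t(cbind(-cen[, 2], cen[, 1], 0))))
  Qr <- qr.Q(qr(rigid))
  v <- rnorm(3 * length(idx))
  v <- v - Qr %*% crossprod(Qr, v)
  v <- 0.5 * v / sqrt(sum(v^2))      # small amplitude keeps the fit linear
  dirvec <- matrix(v, length(idx), 3, byrow = TRUE)
  frames <- lapply(seq(-1, 1, length.out = 9), function(a) {
    f <- s$coords[[1]]
    f[idx, ] <- f[idx, ] + a * dirvec
    f
  })
  p1 <- pca_projection(xl_trajectory(s, frames))
  expect_equal(p1$explained_variance[1] / sum(p1$explained_variance), 1,
               tolerance = 1e-6)

  static <- xl_trajectory(s, rep(list(s$coords[[1]]), 4))
  p0 <- pca_projection(static)
  expect_lt(sum(p0$explained_variance), 1e-12)

  tr <- simulate_noise_trajectory(s, 0.4, 10, seed = 21)
  p <- pca_projection(tr, n_components = 3)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_equal(sum(p$explained_variance), p$total_variance, tolerance = 1e-8)

  # oracle route: superpose identically, then eigendecompose the covariance
  sub <- lapply(tr$frames, function(f) f[idx, , drop = FALSE])
  fitted <- xldyn:::fit_frames(sub, sub[[1]])
  mref <- Reduce(`+`, fitted) / length(fitted)
  fitted <- xldyn:::fit_frames(sub, mref)
  X <- t(vapply(fitted, function(f) as.vector(t(f)), numeric(3 * length(idx))))
  orc <- pca_oracle(X)
  expect_equal(p$explained_variance, orc$values[seq_along(p$explained_variance)],
               tolerance = 1e-8)
  for (j in 1:3) {
    expect_equal(abs(sum(p$components[, j] * orc$vectors[, j])), 1,
                 tolerance = 1e-8)
  }
})

test_that("trajectory statistics are invariant under per-frame rigid transforms", {
  s <- toy_chain(20, "helix")
  tr <- simulate_noise_trajectory(s, 0.3, 12, seed = 33)
  set.seed(99)
  wob <- xl_trajectory(s, lapply(tr$frames, function(f) {
    apply_transform(rotation_transform(rnorm(3), runif(1, 0, 2),
                                       t = rnorm(3, sd = 20)), f)
  }))

  expect_equal(rmsd_series(tr), rmsd_series(wob), tolerance = 1e-6)
  expect_equal(rmsf(tr), rmsf(wob), tolerance = 1e-6)

  ct <- native_contacts(tr)
  if (nrow(ct)) {
    expect_equal(q_series(tr, ct), q_series(wob, ct), tolerance = 1e-6)
  }
  p1 <- pca_projection(tr)
  p2 <- pca_projection(wob)
  expect_equal(p1$explained_variance, p2$explained_variance, tolerance = 1e-6)
})
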