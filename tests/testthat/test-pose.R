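test_that("score_pose reflects planted geometry, displacement and clashes", {
  scene <- planted_scene(seed = 5)
  sc <- score_pose(scene$pose, scene$receptor, scene$ligand, scene$links,
                   receptor_proteins = "REC", ligand_proteins = "LIG")
  expect_equal(sc$n_satisfied, 5)       # the 5 planted-consistent links
  expect_equal(sc$n_mappable, 7)
  expect_equal(sc$clash_count, 0)
  expect_true(sc$passed)

  far <- xl_pose("far", compose_transforms(
    translation_transform(c(200, 0, 0)), scene$pose$transform))
  sc_far <- score_pose(far, scene$receptor, scene$ligand, scene$links,
                       "REC", "LIG")
  expect_equal(sc_far$n_satisfied, 0)
  expect_false(sc_far$passed)

  # ligand at the identity pose overlays the receptor's first copy
  # atom-for-atom (same generator parametrisation) -> guaranteed clashes
  ontop <- xl_pose("ontop", identity_transform())
  sc_cl <- score_pose(ontop, scene$receptor, scene$ligand, scene$links,
                      "REC", "LIG", clash_cutoff = 3.0)
  expect_gt(sc_cl$clash_count, 0)
  expect_false(sc_cl$passed)

  expect_error(score_pose(scene$pose, scene$receptor, scene$ligand,
                          scene$links, "WRONG", "LIG"),
               "not assigned")
})

test_that("score_pose is invariant under a common rigid transform of the scene", {
  scene <- planted_scene(seed = 9)
  sc0 <- score_pose(scene$pose, scene$receptor, scene$ligand, scene$links,
                    "REC", "LIG")
  xf <- rotation_transform(c(2, -1, 1), 1.1, t = c(30, -8, 12))
  rec2 <- transform_assembly(scene$receptor, xf)
  # the posed ligand must move with the scene: pose' = xf o pose
  pose2 <- xl_pose("moved", compose_transforms(xf, scene$pose$transform))
  sc1 <- score_pose(pose2, rec2, scene$ligand, scene$links, "REC", "LIG")
  expect_equal(sc1$n_satisfied, sc0$n_satisfied)
  expect_equal(sc1$clash_count, sc0$clash_count)
})

test_that("filter_poses and truncate_pose_list apply the documented order", {
  tab <- data.frame(pose_id = c("a", "b", "c"),
                    n_satisfied = c(5L, 2L, 3L),
                    n_mappable = 7L,
                    clash_count = c(0L, 0L, 1L),
                    passed = NA)
  expect_identical(filter_poses(tab, min_satisfied = 3, max_clash = 0), "a")
  expect_identical(filter_poses(tab[0, ], 3, 0), character(0))
  expect_identical(filter_poses(tab, 0, Inf), c("a", "b", "c"))

  set.seed(1)
  big <- data.frame(pose_id = sprintf("p%02d", 1:40),
                    n_satisfied = rep(c(5L, 4L), 20),
                    n_mappable = 7L,
                    clash_count = rep(c(0L, 1L), each = 20),
                    passed = NA)
  kept <- truncate_pose_list(big, 30)
  expect_length(kept, 30)
  # ties resolve by pose_id so repeated runs agree
  expect_identical(kept, truncate_pose_list(big[sample(40), ], 30))
  expect_length(truncate_pose_list(big, 100), 40)
})

test_that("pose features are rigid-motion meaningful", {
  scene <- planted_scene(seed = 2)
  lig <- scene$ligand
  p0 <- xl_pose("p0", identity_transform())
  p1 <- xl_pose("p1", identity_transform())
  d <- 17.3
  p2 <- xl_pose("p2", translation_transform(c(d, 0, 0)))
  feats <- featurize_poses(list(p0, p1, p2), lig)
  n_ca <- length(select_atoms(lig, atom_selection(element_class = "calpha")))
  expect_equal(ncol(feats), 3 * n_ca)
  expect_equal(feats["p0", ], feats["p1", ])
  expect_equal(sqrt(sum((feats["p2", ] - feats["p0", ])^2)), d * sqrt(n_ca),
               tolerance = 1e-9)
  expect_error(featurize_poses(list(p0), lig,
                               atom_selection(chains = "none")),
               "empty")
})

test_that("ward_cluster matches the Lance-Williams oracle and handles edge cases", {
  # clear separation
  f1 <- matrix(c(0, 1, 10), ncol = 1)
  cl <- ward_cluster(f1, 2)
  expect_true(same_partition(cl$labels, c(1, 1, 2)))

  # k = n -> singletons
  cl_n <- ward_cluster(f1, 3)
  expect_equal(sort(unname(cl_n$labels)), 1:3)

  # duplicates always co-cluster
  f2 <- rbind(c(0, 0), c(0, 0), c(5, 5), c(9, 1))
  cl2 <- ward_cluster(f2, 3)
  expect_equal(cl2$labels[[1]], cl2$labels[[2]])

  # oracle equivalence on random instances <= 8 points, several k
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    for (k in 2:min(4, n - 1)) {
      got <- ward_cluster(X, k)$labels
      want <- ward_oracle_labels(X, k)
      expect_true(same_partition(got, want),
                  label = sprintf("ward oracle rep=%d n=%d k=%d", rep, n, k))
    }
  }

  # row-order invariance up to label permutation
  set.seed(8)
  X <- matrix(rnorm(21), 7, 3)
  rownames(X) <- paste0("p", 1:7)
  perm <- sample(7)
  a <- ward_cluster(X, 3)$labels
  b <- ward_cluster(X[perm, ], 3)$labels[rownames(X)]
  expect_true(same_partition(a, b))

  # heights non-decreasing along merges
  expect_true(all(diff(ward_cluster(X, 2)$heights) >= -1e-12))
  expect_error(ward_cluster(X, 0), "k must be")
  expect_error(ward_cluster(X, 8), "k must be")
})

test_that("cluster representatives are medoids (real members, minimal summed distance)", {
  X <- rbind(c(0, 0), c(1, 0), c(0.4, 0), c(10, 10), c(11, 10))
  rownames(X) <- paste0("p", 1:5)
  cl <- ward_cluster(X, 2)
  for (g in unique(cl$labels)) {
    members <- names(cl$labels)[cl$labels == g]
    dm <- as.matrix(dist(X[members, , drop = FALSE]))
    best <- members[which.min(rowSums(dm))]
    expect_identical(unname(cl$representatives[as.character(g)]), best)
  }
})

test_that("planted-pose recovery: filter keeps the truth and rejects all decoys", {
  for (seed in 1:10) {
    scene <- planted_scene(seed = seed, n_true = 5, n_false = 2,
                           n_decoys = 20, min_displacement = 50)
    poses <- c(list(scene$pose), scene$decoys)
    scores <- lapply(poses, function(p) {
      score_pose(p, scene$receptor, scene$ligand, scene$links, "REC", "LIG")
    })
    kept <- filter_poses(scores, min_satisfied = 3, max_clash = 0)
    expect_identical(kept, "planted",
                     label = sprintf("planted recovery seed=%d", seed))
  }
})

test_that("pose lists round-trip through the delimited format", {
  scene <- planted_scene(seed = 3, n_decoys = 4)
  poses <- c(list(scene$pose), scene$decoys)
  path <- tempfile(fileext = ".tsv")
  write_pose_list(poses, path)
  back <- read_pose_list(path)
  expect_equal(length(back), 5)
  for (i in seq_along(poses)) {
    expect_equal(back[[i]]$transform$R, poses[[i]]$transform$R,
                 tolerance = 1e-8)
    expect_equal(back[[i]]$transform$t, poses[[i]]$transform$t,
                 tolerance = 1e-8)
  }
})
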