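test_that("distance budgets follow spacer + 2 x side chain + dynamics", {
  expect_equal(distance_budget("CDI"), 21.2)
  expect_equal(distance_budget("DSBU"), 31.1)
  expect_equal(distance_budget(linker_chemistry("ZERO", 0)), 18.6)
  expect_error(linker_chemistry("BAD", -1), ">= 0")
  expect_error(distance_budget("NOPE"), "unregistered")
})

test_that("cross-link tables read, validate and round-trip", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("protein_a,res_a,protein_b,res_b,linker,score",
               "E1,82,E2,150,DSBU,110.5",
               "E1,300,E2,98,CDI,87.0"), path)
  links <- read_crosslink_table(path)
  expect_s3_class(links, "xl_crosslinks")
  expect_equal(nrow(links), 2)
  expect_equal(links$res_a, c(82L, 300L))
  expect_equal(links$linker, c("DSBU", "CDI"))
  expect_match(links$source_row[1], ":2$")   # provenance points at file row

  out <- tempfile(fileext = ".tsv")
  write_crosslink_table(links, out)
  links2 <- read_crosslink_table(out)
  expect_equal(links2$protein_a, links$protein_a)
  expect_equal(links2$res_b, links$res_b)
  expect_equal(links2$score, links$score)

  writeLines(c("protein_a,res_a,protein_b,res_b,linker",
               "E1,0,E2,5,DSBU"), path)
  expect_error(read_crosslink_table(path), "residue number")
  writeLines(c("protein_a,res_a,protein_b,linker", "E1,1,E2,DSBU"), path)
  expect_error(read_crosslink_table(path), "missing required")
})

test_that("mapping resolves homo-oligomer ambiguity by the minimum over copies", {
  # trimer of a 5-residue chain: copies at 0, +40 and +10 along x.
  # A link REC:1 -- REC2:1 between different chains has candidates at
  # 40, 10 and 30 A; the mapped distance must be the 10 A one.
  s <- ca_structure(cbind(100 * (0:4), 0, 0), res_name = "LYS")
  a <- build_assembly(s, list(identity_transform(),
                              translation_transform(c(40, 0, 0)),
                              translation_transform(c(10, 0, 0))))
  links <- crosslink_table(data.frame(
    protein_a = "P", res_a = 1, protein_b = "P", res_b = 1,
    linker = "DSBU"))
  m <- map_crosslinks(a, links,
                      chain_assignment = list(P = unique(a$atoms$chain_label)))
  expect_true(m$mappable)
  expect_equal(m$min_distance, 10)
  expect_equal(m$n_candidates, 3)       # self-pairing excluded, 3 inter-copy pairs
  expect_true(m$satisfied)              # 10 <= 31.1

  # residue beyond the chain -> unmappable but reported
  links2 <- crosslink_table(data.frame(
    protein_a = "P", res_a = 1, protein_b = "P", res_b = 99,
    linker = "DSBU"))
  m2 <- map_crosslinks(a, links2,
                       chain_assignment = list(P = unique(a$atoms$chain_label)))
  expect_false(m2$mappable)
  expect_false(m2$satisfied)

  expect_error(map_crosslinks(a, links, chain_assignment = list(Q = "c1/A")),
               "no chain assignment")
})

test_that("satisfaction counts follow the per-link flags and denominators", {
  s <- ca_structure(cbind(c(0, 100), 0, 0), res_name = "LYS")
  a <- build_assembly(s, list(identity_transform(),
                              translation_transform(c(0, 20, 0)),
                              translation_transform(c(0, 500, 0))))
  ch <- list(P = unique(a$atoms$chain_label))
  # 3 satisfiable links (20 A inter-copy), 2 violated (same chain, 100 A),
  # 1 unmappable -> (n_total, n_mappable, n_satisfied) = (6, 5, 3)
  links <- crosslink_table(data.frame(
    protein_a = "P", res_a = c(1, 1, 2, 1, 2, 1),
    protein_b = "P", res_b = c(1, 1, 2, 2, 1, 77),
    linker = "DSBU"))
  m <- map_crosslinks(a, links, ch)
  rep <- evaluate_satisfaction(m)
  expect_equal(rep$n_total, 6)
  expect_equal(rep$n_mappable, 5)
  expect_equal(rep$n_satisfied, 3)
  expect_lte(rep$n_satisfied, rep$n_mappable)
  expect_lte(rep$n_mappable, rep$n_total)
  expect_equal(evaluate_satisfaction(m, count_unmappable = TRUE)$denominator, 6)

  out <- tempfile(fileext = ".tsv")
  write_satisfaction_report(rep, out)
  tab <- read.delim(out)
  expect_equal(nrow(tab), 6)
  expect_equal(sum(tab$satisfied), 3)
})

test_that("satisfaction is monotone in budget and rigid-invariant; oracle agrees", {
  scene <- planted_scene(seed = 42)
  a <- transform_assembly(scene$ligand, scene$pose$transform)
  comb <- xldyn:::combine_assemblies(scene$receptor, a)
  ch <- list(REC = grep("^R/", unique(comb$atoms$chain_label), value = TRUE),
             LIG = grep("^L/", unique(comb$atoms$chain_label), value = TRUE))

  links_d <- scene$links
  links_c <- links_d
  links_c$linker <- "CDI"
  m_d <- map_crosslinks(comb, links_d, ch)
  m_c <- map_crosslinks(comb, links_c, ch)
  expect_identical(m_c$min_distance, m_d$min_distance)  # geometry unchanged
  expect_lte(sum(m_c$satisfied), sum(m_d$satisfied))    # CDI budget <= DSBU

  # min over copies <= every candidate distance, and equals brute force
  cands <- attr(m_d, "candidates")
  for (i in seq_len(nrow(m_d))) {
    expect_true(all(m_d$min_distance[i] <= cands[[i]]$distance + 1e-12))
    oracle <- bruteforce_min_distance(comb, m_d$res_a[i], m_d$res_b[i],
                                      ch$REC, ch$LIG)
    expect_equal(m_d$min_distance[i], oracle, tolerance = 1e-9)
  }

  # global rigid transform leaves satisfaction flags unchanged
  xf <- rotation_transform(c(1, 2, 3), 0.83, t = c(-40, 13, 7))
  m_rot <- map_crosslinks(transform_assembly(comb, xf), links_d, ch)
  expect_identical(m_rot$satisfied, m_d$satisfied)
  expect_equal(m_rot$min_distance, m_d$min_distance, tolerance = 1e-9)
})
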