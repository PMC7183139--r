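test_that("the fixture library is the six catalogued compounds", {
  lib <- fixture_library()
  expect_length(lib, 6L)
  expect_false(anyDuplicated(names(lib)) > 0L)
  expect_true(all(vapply(lib, inherits, FALSE, "Molecule")))
  # the query carries a protonated terminal ammonium
  am <- lib$Amlodipine
  ammonium <- am$atoms$element == "N" & am$atoms$charge == 1L &
    am$atoms$implicit_h == 3L
  expect_equal(sum(ammonium), 1L)
})

test_that("donor knockouts eliminate donors deterministically", {
  am <- fixture_library()$Amlodipine
  dec <- generate_decoys(am, "remove_donor", 5L, 1L)
  expect_length(dec, 5L)
  for (d in dec) {
    expect_lt(count_n_ohnh(d), 2L)
    expect_equal(count_features(d, "donor"), 0L)
  }
  # determinism: identical SMILES across runs
  s1 <- vapply(generate_decoys(am, "none", 3L, 1L), write_smiles, "")
  s2 <- vapply(generate_decoys(am, "none", 3L, 1L), write_smiles, "")
  expect_identical(s1, s2)

  expect_error(generate_decoys(parse_smiles("c1ccccc1", "benzene"),
                               "remove_donor"), "no donors")
  expect_error(generate_decoys(parse_smiles("CCO", "ethanol"),
                               "remove_hydrophobic"), "halogenated")
})

test_that("hydrophobic knockouts excise the halogenated ring", {
  am <- fixture_library()$Amlodipine
  d <- generate_decoys(am, "remove_hydrophobic", 1L)[[1L]]
  expect_equal(nrow(d$atoms), nrow(am$atoms) - 7L)  # six ring C + Cl
  expect_false("Cl" %in% d$atoms$element)
  # the edit is a valid molecule that still embeds
  e <- embed_conformers(d, 1L, 1L)
  expect_length(e$conformers, 1L)
})

test_that("scrambled-geometry decoys keep the graph but not the pose", {
  am <- fixture_library()$Amlodipine
  d <- generate_decoys(am, "scramble_geometry", 2L, 9L)
  expect_identical(d[[1L]]$atoms$element, am$atoms$element)
  expect_length(d[[1L]]$conformers, 1L)
  expect_false(identical(d[[1L]]$conformers[[1L]], d[[2L]]$conformers[[1L]]))
})

test_that("toy pockets are feasible, self-describing and seeded", {
  pk <- generate_toy_pocket(5L, 3L, 2L, 7L)
  expect_equal(pk$manifest$n_residues, 5L)
  expect_equal(pk$manifest$n_planted_hbonds, 3L)
  expect_equal(pk$manifest$n_site_members, 2L)
  expect_equal(nrow(pk$site), 2L)

  pk2 <- generate_toy_pocket(5L, 3L, 2L, 7L)
  expect_identical(pk$pdb, pk2$pdb)
  pk3 <- generate_toy_pocket(5L, 3L, 2L, 8L)
  expect_false(identical(pk$pdb, pk3$pdb))

  expect_error(generate_toy_pocket(2L, 3L, 0L), "infeasible")
  expect_error(generate_toy_pocket(2L, 0L, 3L), "infeasible")
})

test_that("pocket bundles round-trip through their file formats", {
  pk <- generate_toy_pocket(4L, 2L, 1L, 5L)
  d <- tempfile("bundle")
  write_toy_pocket(pk, d)
  expect_true(all(file.exists(file.path(d, c("pocket.pdb", "pose.sdf",
                                             "site.json", "manifest.json")))))
  pose <- read_sdf(file.path(d, "pose.sdf"))[[1L]]
  expect_identical(pose$atoms$element, pk$pose$atoms$element)
  expect_equal(pose$conformers[[1L]], pk$pose$conformers[[1L]],
               tolerance = 1e-3)
  prot <- read_protein(file.path(d, "pocket.pdb"))
  expect_equal(nrow(unique(prot[, c("chain", "resno")])),
               4L + 2L)  # planted residues plus two far decoys
})
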