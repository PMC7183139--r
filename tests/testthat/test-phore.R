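test_that("feature perception finds the expected chemistry", {
  am <- embed_conformers(fixture_library()$Amlodipine, 1L, 42L)
  f <- perceive_features(am, 1L)
  expect_gte(sum(f$kind == "donor"), 2L)
  expect_gte(sum(f$kind == "hydrophobic"), 4L)
  # donor directions are unit vectors
  dd <- f[f$kind == "donor", ]
  expect_equal(sqrt(dd$dx^2 + dd$dy^2 + dd$dz^2), rep(1, nrow(dd)),
               tolerance = 1e-9)

  bz <- embed_conformers(parse_smiles("c1ccccc1", "benzene"), 1L, 1L)
  fb <- perceive_features(bz, 1L)
  expect_identical(fb$kind, "hydrophobic")
  # ring centroid sits at the geometric center
  expect_equal(as.numeric(fb[1, c("x", "y", "z")]),
               colMeans(bz$conformers[[1L]]), tolerance = 1e-9)

  w <- embed_conformers(parse_smiles("O", "water"), 1L, 1L)
  fw <- perceive_features(w, 1L)
  expect_identical(sort(fw$kind), c("acceptor", "donor"))

  expect_error(perceive_features(fixture_library()$Amlodipine, 1L),
               "missing conformer")
})

test_that("the reference model is the documented six-feature arrangement", {
  mod <- build_reference_model(42L)
  core <- mod$features[mod$features$kind != "exclusion", ]
  expect_equal(nrow(core), 6L)
  expect_identical(as.vector(table(core$kind)[c("donor", "hydrophobic")]),
                   c(2L, 4L))
  expect_identical(core$label,
                   c("HBD1", "HBD2", paste0("Hydrophobic", 1:4)))
  expect_gte(sum(mod$features$kind == "exclusion"), 1L)

  # rebuilds are byte-identical; the shipped JSON is the same model
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  save_model(mod, f1)
  save_model(build_reference_model(42L), f2)
  expect_identical(readLines(f1), readLines(f2))
  shipped <- reference_model()
  expect_equal(shipped$features$x, mod$features$x, tolerance = 1e-12)
  expect_identical(shipped$features$label, mod$features$label)

  # losing the chlorophenyl leaves too few hydrophobics for a model build
  nohalo <- generate_decoys(fixture_library()$Amlodipine,
                            "remove_hydrophobic", 1L)[[1L]]
  expect_lt(count_features(nohalo, "hydrophobic"), 4L)
})

test_that("model JSON round trip is lossless and schema violations error", {
  mod <- reference_model()
  p <- tempfile(fileext = ".json")
  save_model(mod, p)
  back <- load_model(p)
  expect_equal(back$features$x, mod$features$x, tolerance = 1e-12)
  expect_identical(back$features$kind, mod$features$kind)
  expect_identical(back$require_all, mod$require_all)

  bad1 <- tempfile(); writeLines('{"name": "x"}', bad1)
  expect_error(load_model(bad1), "features")
  bad2 <- tempfile()
  jsonlite::write_json(list(name = "x", features = list(list(
    label = "a", kind = "donor", center = c(0, 0, 0), radius = 0))),
    bad2, auto_unbox = TRUE)
  expect_error(load_model(bad2), "radius")
})

test_that("identity and rigidly moved conformations match at zero RMSD", {
  mod <- reference_model()
  am <- embed_conformers(fixture_library()$Amlodipine, 1L, 42L)
  lf <- perceive_features(am, 1L)
  res <- match_features(lf, mod, 1.5, ligand_coords = am$conformers[[1L]])
  expect_true(res$matched)
  expect_lt(res$rmsd, 1e-6)
  expect_equal(res$n_exclusion_clashes, 0L)
  expect_length(res$mapping, 6L)

  for (seed in 1:10) {
    moved <- rigidly_move(am, seed)
    lf2 <- perceive_features(moved, 1L)
    res2 <- match_features(lf2, mod, 1.5,
                           ligand_coords = moved$conformers[[1L]])
    expect_true(res2$matched)
    expect_lt(res2$rmsd, 1e-6)
    expect_identical(res2$mapping, res$mapping)
  }
})

test_that("matching agrees with the exhaustive oracle on random instances", {
  n_match <- 0L
  for (seed in 1:150) {
    inst <- random_match_instance(seed)
    mine <- match_features(inst$ligand_features, inst$model, 1.5)
    ref <- brute_force_match(inst$ligand_features, inst$model, 1.5)
    expect_identical(mine$matched, ref$matched, info = paste("seed", seed))
    if (ref$matched) {
      n_match <- n_match + 1L
      expect_equal(mine$rmsd, ref$rmsd, tolerance = 1e-9,
                   info = paste("seed", seed))
    }
  }
  expect_gt(n_match, 20L)  # the instance mix must exercise both outcomes
  expect_lt(n_match, 130L)
})

test_that("tolerance is monotone: a match survives any larger tolerance", {
  mod <- reference_model()
  am <- embed_conformers(fixture_library()$Amlodipine, 1L, 42L)
  for (seed in 1:5) {
    pert <- perturb_conformer(am, 0.35, seed)
    lf <- perceive_features(pert, 1L)
    taus <- c(0.8, 1.2, 1.5, 2.5)
    got <- vapply(taus, function(tau)
      match_features(lf, mod, tau, ligand_coords = pert$conformers[[1L]])$matched,
      FALSE)
    expect_true(all(diff(as.integer(got)) >= 0L),
                info = paste(seed, paste(got, collapse = ",")))
  }
})

test_that("an exclusion sphere on any matched ligand atom vetoes the match", {
  mod <- reference_model()
  am <- embed_conformers(fixture_library()$Amlodipine, 1L, 42L)
  lf <- perceive_features(am, 1L)
  X <- am$conformers[[1L]]
  base <- match_features(lf, mod, 1.5, ligand_coords = X)
  expect_true(base$matched)
  for (atom in c(1L, 8L, 15L, 28L)) {
    mod2 <- mod
    mod2$features <- rbind(mod2$features,
                           .feature_row("Veto", "exclusion", X[atom, ], 0.5))
    res <- match_features(lf, mod2, 1.5, ligand_coords = X)
    expect_false(res$matched, info = paste("atom", atom))
    expect_gt(res$n_exclusion_clashes, 0L)
  }
})

test_that("dropping a model feature never destroys an existing match", {
  for (seed in 1:40) {
    inst <- random_match_instance(seed)
    full <- match_features(inst$ligand_features, inst$model, 1.5)
    core <- which(inst$model$features$kind != "exclusion")
    if (length(core) <= 1L) next
    for (drop in core) {
      sub <- inst$model
      sub$features <- sub$features[-drop, , drop = FALSE]
      res <- match_features(inst$ligand_features, sub, 1.5)
      if (full$matched) expect_true(res$matched,
                                    info = paste("seed", seed, "drop", drop))
    }
  }
})

test_that("screening a molecule returns the ensemble-best result", {
  mod <- reference_model()
  res <- screen_molecule(fixture_library()$Amlodipine, mod, 5L, 42L, 1.5)
  expect_true(res$matched)
  expect_equal(res$conformer_index, 1L)

  bz <- parse_smiles("c1ccccc1", "benzene")
  rb <- screen_molecule(bz, mod, 5L, 42L, 1.5)
  expect_false(rb$matched)
  expect_match(rb$diagnostics, "too few donor")

  r0 <- screen_molecule(fixture_library()$Amlodipine, mod, 0L, 42L, 1.5)
  expect_false(r0$matched)
  expect_match(r0$diagnostics, "no conformers")
})

test_that("small perturbations keep matching, large ones destroy it", {
  mod <- reference_model()
  am <- embed_conformers(fixture_library()$Amlodipine, 1L, 42L)
  ok_small <- ok_large <- 0L
  for (seed in 1:20) {
    small <- perturb_conformer(am, 0.1, seed)
    fs <- perceive_features(small, 1L)
    if (match_features(fs, mod, 1.5,
                       ligand_coords = small$conformers[[1L]])$matched)
      ok_small <- ok_small + 1L
    large <- perturb_conformer(am, 10, seed)
    fl <- perceive_features(large, 1L)
    if (match_features(fl, mod, 1.5,
                       ligand_coords = large$conformers[[1L]])$matched)
      ok_large <- ok_large + 1L
  }
  expect_equal(ok_small, 20L)
  expect_lte(ok_large, 1L)
})
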