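test_that("the six-compound screen reproduces the drug-likeness outcome", {
  lib <- fixture_library()
  ht <- run_screen(lib, model = NULL,
                   screen_config(do_phore = FALSE))
  expect_equal(nrow(ht), 6L)
  expect_identical(ht$id, names(lib))
  expect_true(all(ht$druglike))
  expect_identical(ht$n_violations, c(0L, 0L, 1L, 1L, 0L, 0L))
  expect_true(all(is.na(ht$rank)))
})

test_that("a feature-poor library yields zero ranked hits but full rows", {
  alkanes <- list(hexane = "CCCCCC", heptane = "CCCCCCC",
                  cyclohexane = "C1CCCCC1")
  ht <- run_screen(alkanes, reference_model(),
                   screen_config(n_conformers = 2L))
  expect_equal(nrow(ht), 3L)
  expect_true(all(!ht$matched))
  expect_true(all(is.na(ht$rank)))
  expect_false(anyNA(ht$mw))
})

test_that("per-compound failures are recorded without aborting", {
  ht <- run_screen(list(ok = "CCO", broken = "C1CC"), model = NULL,
                   screen_config(do_phore = FALSE))
  expect_equal(nrow(ht), 2L)
  expect_match(ht$error[2L], "unclosed ring")
  expect_false(is.na(ht$mw[1L]))
  expect_error(run_screen(list(bad = "C1CC"), NULL,
                          screen_config(do_phore = FALSE)), "all compounds")
})

test_that("ranked hits on an active/decoy library are exclusively actives", {
  lib6 <- fixture_library()
  actives <- generate_decoys(lib6$Amlodipine, "none", 4L, 1L)
  decoys <- generate_decoys(lib6$Amlodipine, "remove_donor", 12L, 1L)
  ht <- run_screen(c(actives, decoys), reference_model(),
                   screen_config(n_conformers = 3L))
  hits <- ht$id[!is.na(ht$rank)]
  expect_gt(length(hits), 0L)
  expect_true(all(grepl("_none_", hits)))
  # ranks are contiguous from 1
  expect_identical(sort(ht$rank[!is.na(ht$rank)]), seq_along(hits))
})

test_that("the pipeline equals the manual composition of its stages", {
  mod <- reference_model()
  lib <- fixture_library()[c("Amlodipine", "Zinc33254827")]
  cfg <- screen_config(n_conformers = 2L)
  ht <- run_screen(lib, mod, cfg)
  for (i in seq_along(lib)) {
    d <- descriptor_set(lib[[i]])
    r <- lipinski_report(d)
    s <- screen_molecule(lib[[i]], mod, cfg$n_conformers, cfg$seed,
                         cfg$tolerance)
    expect_equal(ht$tpsa[i], d$tpsa)
    expect_equal(ht$n_violations[i], r$n_violations)
    expect_equal(ht$matched[i], s$matched)
    if (s$matched) expect_equal(ht$phore_rmsd[i], s$rmsd)
  }
})

test_that("hit reports are byte-deterministic", {
  lib <- fixture_library()[c("Amlodipine", "Zinc20267861")]
  cfg <- screen_config(n_conformers = 2L)
  f1 <- tempfile(); f2 <- tempfile()
  write_hits_table(run_screen(lib, reference_model(), cfg), f1)
  write_hits_table(run_screen(lib, reference_model(), cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1) + 10L),
                   readBin(f2, "raw", file.size(f2) + 10L))
  # fixed header and row count
  lines <- readLines(f1)
  expect_length(lines, 3L)
  expect_identical(strsplit(lines[1L], "\t")[[1L]][1:4],
                   c("id", "smiles", "mw", "logp"))

  empty <- run_screen(list(hexane = "CCCCCC"), NULL,
                      screen_config(do_phore = FALSE))
  f3 <- tempfile()
  write_hits_table(empty[0L, ], f3)
  expect_length(readLines(f3), 1L)
})
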