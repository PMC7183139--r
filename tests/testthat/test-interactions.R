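make_pocket_files <- function(n_res, n_hb, n_site, seed) {
  pk <- generate_toy_pocket(n_res, n_hb, n_site, seed)
  d <- tempfile("pocket")
  write_toy_pocket(pk, d)
  list(prot = read_protein(file.path(d, "pocket.pdb")),
       pose = read_sdf(file.path(d, "pose.sdf"))[[1L]],
       site = if (nrow(pk$site) > 0L)
         load_active_site(file.path(d, "site.json")) else NULL,
       manifest = jsonlite::read_json(file.path(d, "manifest.json"),
                                      simplifyVector = TRUE),
       pk = pk)
}

test_that("PDB reading populates chains, residues and elements", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1 N    GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2 CA   GLY A   1       1.450   0.000   0.000  1.00  0.00           C",
    "END"), p)
  prot <- read_protein(p)
  expect_equal(nrow(prot), 2L)
  expect_identical(prot$chain, c("A", "A"))
  expect_identical(prot$elesy, c("N", "C"))
  expect_identical(prot$resid, c("GLY", "GLY"))

  empty <- tempfile(fileext = ".pdb")
  writeLines("", empty)
  expect_error(read_protein(empty))
  expect_error(read_protein(tempfile(fileext = ".pdb")), "no such file")
})

test_that("contacts obey the cutoff and deduplicate residues", {
  # one ligand atom 3.0 A from a protein atom
  pose <- new_molecule("probe",
    data.frame(element = "C", charge = 0L, implicit_h = 4L,
               aromatic = FALSE, stereo = "", bracket = FALSE),
    data.frame(a = integer(0), b = integer(0), order = character(0),
               in_ring = logical(0)),
    conformers = list(matrix(c(0, 0, 0), 1L, 3L)))
  p <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1 CA   ALA A   5       3.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2 CB   ALA A   5       3.900   0.000   0.000  1.00  0.00           C",
    "END"), p)
  prot <- read_protein(p)
  ct <- find_contacts(pose, prot, cutoff = 4.5)
  expect_equal(nrow(ct), 2L)            # both atoms of one residue
  expect_equal(length(unique(ct$residue)), 1L)
  expect_equal(ct$distance[1L], 3.0, tolerance = 1e-6)
  expect_equal(nrow(find_contacts(pose, prot, cutoff = 2.0)), 0L)
  expect_error(find_contacts(pose, prot, cutoff = -1), "cutoff")
})

test_that("hydrogen bonds require both distance and angle", {
  pk <- make_pocket_files(5L, 3L, 0L, 11L)
  hb <- find_hbonds(pk$pose, pk$prot)
  expect_equal(nrow(hb), 3L)
  expect_true(all(hb$angle > 179))
  expect_true(all(abs(hb$distance - 2.9) < 0.01))

  # stretch the planted donors beyond 3.5 A: the pocket geometry is radial
  # in the y-z plane around the x-axis ligand, so scaling y/z moves every
  # donor nitrogen from 2.9 to 4.0 A while keeping D-H...A collinear
  stretched <- pk$prot
  stretched$y <- stretched$y * (4.0 / 2.9)
  stretched$z <- stretched$z * (4.0 / 2.9)
  expect_equal(nrow(find_hbonds(pk$pose, stretched)), 0L)

  # bend the explicit hydrogens to ~90 degrees: angle criterion kills all
  bent <- pk$prot
  hrows <- which(bent$elesy == "H")
  for (r in hrows) {
    nrow_ <- which(bent$elesy == "N" & bent$resno == bent$resno[r])
    np <- as.numeric(bent[nrow_, c("x", "y", "z")])
    bent[r, c("x", "y", "z")] <- np + c(1.0, 0, 0)  # perpendicular N-H
  }
  expect_equal(nrow(find_hbonds(pk$pose, bent)), 0L)
})

test_that("interaction summaries recover the planted ground truth", {
  pk <- make_pocket_files(5L, 3L, 2L, 7L)
  it <- summarize_interactions(pk$pose, pk$prot, pk$site)
  expect_length(it$surrounding_residues, 5L)
  expect_equal(it$n_hbonds, 3L)
  expect_equal(it$n_active_site_interactions, 2L)
  expect_true(is.na(it$external_score))

  it2 <- summarize_interactions(pk$pose, pk$prot, pk$site,
                                external_score = -8.1)
  expect_equal(it2$external_score, -8.1)

  # minimal pocket
  mini <- make_pocket_files(1L, 0L, 0L, 0L)
  itm <- summarize_interactions(mini$pose, mini$prot, NULL)
  expect_length(itm$surrounding_residues, 1L)
  expect_equal(itm$n_hbonds, 0L)

  # ligand far from everything
  far <- pk$pose
  far$conformers[[1L]] <- far$conformers[[1L]] + 100
  itf <- summarize_interactions(far, pk$prot, pk$site)
  expect_length(itf$surrounding_residues, 0L)
  expect_equal(itf$n_hbonds, 0L)
  expect_equal(itf$n_active_site_interactions, 0L)
})

test_that("contacts are invariant under a joint rigid transform", {
  pk <- make_pocket_files(4L, 2L, 1L, 3L)
  base <- summarize_interactions(pk$pose, pk$prot, pk$site)
  for (seed in 1:5) {
    set.seed(seed)
    R <- rot3(runif(3, 0, 2 * pi)); tv <- runif(3, -10, 10)
    pose2 <- pk$pose
    pose2$conformers[[1L]] <- sweep(pose2$conformers[[1L]] %*% R, 2, tv, `+`)
    prot2 <- pk$prot
    XYZ <- as.matrix(prot2[, c("x", "y", "z")])
    prot2[, c("x", "y", "z")] <- sweep(XYZ %*% R, 2, tv, `+`)
    it <- summarize_interactions(pose2, prot2, pk$site)
    expect_identical(sort(it$surrounding_residues),
                     sort(base$surrounding_residues))
    expect_equal(it$n_hbonds, base$n_hbonds)
    expect_equal(it$n_active_site_interactions,
                 base$n_active_site_interactions)
  }
})

test_that("the surrounding set grows monotonically with the cutoff", {
  pk <- make_pocket_files(6L, 2L, 0L, 9L)
  sets <- lapply(c(3.0, 4.5, 6.0, 12.0), function(cc)
    unique(find_contacts(pk$pose, pk$prot, cc)$residue))
  for (i in seq_len(length(sets) - 1L)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1L]]))
  }
  # the far decoy residues only appear at generous cutoffs
  expect_gt(length(sets[[4L]]), length(sets[[2L]]))
})

test_that("the packaged active-site list covers the four pore chains", {
  site <- lvgcc_active_site()
  expect_equal(nrow(site), 32L)
  expect_identical(sort(unique(site$chain)), c("A", "B", "C", "D"))
  expect_true(all(c("SER", "ILE", "THR", "ASN") %in% site$resname))
  expect_true(78 %in% site$resno[site$chain == "A"])
})
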