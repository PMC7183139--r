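test_that("the six fixture SMILES parse to the catalogued formulas and masses", {
  lib <- fixture_library()
  expect_length(lib, 6L)
  expect_false(anyDuplicated(names(lib)) > 0L)

  expect_equal(molecular_formula(lib$Zinc33254827), "C22H25N3O4")
  expect_equal(molecular_formula(lib$Amlodipine), "C20H26ClN2O5+")
  expect_equal(net_charge(lib$Zinc38735350), 2L)
  expect_equal(net_charge(lib$Zinc18204217), -1L)
  expect_equal(net_charge(lib$Zinc67664832), -1L)

  # vendor catalogue masses, 3 decimals
  expect_equal(molecular_weight(lib$Zinc20267861), 485.364, tolerance = 5e-4)
  expect_equal(molecular_weight(lib$Zinc33254827), 395.459, tolerance = 5e-4)
  # the amlodipine query is the ammonium cation as drawn
  expect_equal(round(molecular_weight(lib$Amlodipine), 2), 409.89)
})

test_that("small-molecule parsing handles hydrogens, charges and errors", {
  m <- parse_smiles("C", "methane")
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$implicit_h, 4L)
  expect_equal(net_charge(m), 0L)
  expect_equal(molecular_weight(m), 12.011 + 4 * 1.008, tolerance = 1e-9)

  expect_equal(molecular_formula(parse_smiles("O")), "H2O")
  expect_equal(molecular_formula(parse_smiles("[NH4+]")), "H4N+")

  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles(""), "non-empty")
  expect_error(parse_smiles("C(C)(C)(C)(C)C"), "valence")
  expect_error(parse_smiles("cc"), "not in a ring")
  expect_error(parse_smiles("C?"), "unparsable token")
})

test_that("mass additivity: weight equals formula counts times atomic weights", {
  wts <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, Cl = 35.453,
           S = 32.06)
  for (m in fixture_library()) {
    counts <- table(m$atoms$element)
    manual <- sum(wts[names(counts)] * as.integer(counts)) +
      sum(m$atoms$implicit_h) * wts[["H"]]
    expect_equal(molecular_weight(m), manual, tolerance = 1e-6)
  }
})

test_that("neutralization is pure hydrogen arithmetic", {
  lib <- fixture_library()
  anion <- lib$Zinc18204217
  neutral <- neutralize(anion)
  expect_equal(net_charge(neutral), 0L)
  # exactly one hydrogen added to the phenolate-type oxygen
  expect_equal(molecular_weight(neutral) - molecular_weight(anion), 1.008,
               tolerance = 1e-9)
  expect_equal(molecular_weight(neutral), 502.745, tolerance = 5e-4)
  # heavy-atom skeleton untouched
  expect_identical(neutral$atoms$element, anion$atoms$element)

  # neutral molecules pass through unchanged
  m <- parse_smiles("CCO", "ethanol")
  expect_identical(neutralize(m), m)

  # quaternary ammonium has no removable hydrogen
  expect_error(neutralize(parse_smiles("[N+](C)(C)(C)C")), "no removable")
})

test_that("canonical output round-trips formula and charge", {
  cases <- c(vapply(fixture_library(), function(m) m$smiles, ""),
             "c1cc[nH]c1", "CC(=O)[O-].[NH4+]", "N#Cc1ccccc1O",
             "C/C=C/C", "O=[N+]([O-])c1ccccc1")
  for (smi in cases) {
    m <- parse_smiles(smi, "x")
    m2 <- parse_smiles(write_smiles(m), "x")
    expect_identical(molecular_formula(m2), molecular_formula(m), info = smi)
    expect_identical(net_charge(m2), net_charge(m), info = smi)
    expect_identical(count_rotatable_bonds(m2), count_rotatable_bonds(m),
                     info = smi)
  }
})

test_that("ring perception finds the expected smallest rings", {
  expect_length(perceive_rings(parse_smiles("c1ccccc1")), 1L)
  expect_length(perceive_rings(parse_smiles("c1ccc2ccccc2c1")), 2L)
  expect_length(perceive_rings(parse_smiles("CCO")), 0L)
  rings <- perceive_rings(fixture_library()$Zinc18204217)
  expect_length(rings, 4L)
  expect_true(all(vapply(rings, length, 0L) == 6L))
})
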