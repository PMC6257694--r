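test_that("parsing captures the ethyl acetate connection table", {
  mol <- parse_molfile(builtin_molecules()[["ethyl_acetate"]])
  expect_equal(nrow(mol$atoms), 6)
  expect_equal(nrow(mol$bonds), 5)
  expect_equal(sum(mol$bonds$order == 2), 1)
  expect_equal(sort(mol$atoms$element), c("C", "C", "C", "C", "O", "O"))
  bz <- parse_molfile(builtin_molecules()[["benzene"]])
  expect_equal(c(nrow(bz$atoms), nrow(bz$bonds)), c(6, 6))
})

test_that("properties-block charges supersede atom-block charge codes", {
  txt <- paste(c("", "  t", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 N   0  3  0  0  0  0  0  0  0  0  0  0",
    "    1.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "M  CHG  1   2  -1",
    "M  END"), collapse = "\n")
  mol <- parse_molfile(txt)
  # M CHG resets every atom-block charge, then applies its own pairs
  expect_equal(mol$atoms$charge, c(0L, -1L))
  # without M CHG the atom-block code (+1) stands
  mol2 <- parse_molfile(sub("M  CHG  1   2  -1\n", "", txt, fixed = TRUE))
  expect_equal(mol2$atoms$charge, c(1L, 0L))
})

test_that("malformed input fails with the offending line identified", {
  expect_error(parse_molfile("just one line"), "line 1")
  bad <- strsplit(builtin_molecules()[["benzene"]], "\n")[[1]]
  expect_error(parse_molfile(bad[1:8]), "truncated")
  v3 <- bad
  v3[4] <- "  0  0  0     0  0            999 V3000"
  expect_error(parse_molfile(v3), "V3000")
})

test_that("write-parse round trip preserves the graph for all fixtures", {
  for (nm in names(builtin_molecules())) {
    mol <- parse_molfile(builtin_molecules()[[nm]])
    back <- parse_molfile(write_molfile(mol))
    expect_equal(back$atoms$element, mol$atoms$element, info = nm)
    expect_equal(back$atoms$charge, mol$atoms$charge, info = nm)
    expect_equal(back$atoms$isotope, mol$atoms$isotope, info = nm)
    expect_equal(back$bonds[, c("a1", "a2", "order", "stereo")],
                 mol$bonds[, c("a1", "a2", "order", "stereo")], info = nm)
  }
})

test_that("round trip holds for 200 seeded random molecules", {
  for (s in 1:200) {
    mol <- generate_molecule(s, n_atoms = c(6, 25))
    back <- parse_molfile(write_molfile(mol))
    expect_equal(back$atoms$element, mol$atoms$element)
    expect_equal(back$atoms$charge, mol$atoms$charge)
    expect_equal(back$bonds[, c("a1", "a2", "order")],
                 mol$bonds[, c("a1", "a2", "order")])
  }
})

test_that("tweaked output stores perception and survives re-parsing", {
  bz <- fx("benzene")
  tw <- parse_molfile(write_molfile(bz, tweaked = TRUE))
  expect_true(tw$tweak)
  expect_equal(sum(tw$atoms$aromatic), 6)
  expect_equal(sum(tw$bonds$aromatic), 6)
  # persistence through a second write-parse cycle
  tw2 <- parse_molfile(write_molfile(perceive(tw), tweaked = TRUE))
  expect_true(tw2$tweak)
  cy <- fx("cyclohexane")
  twc <- parse_molfile(write_molfile(cy, tweaked = TRUE))
  expect_false(any(twc$bonds$aromatic))
  expect_error(write_molfile(parse_molfile(builtin_molecules()[["benzene"]]),
                             tweaked = TRUE), "perceived")
})

test_that("a tweaked file reads as the same chemical graph in an outside parser", {
  library(ChemmineR)
  caf <- fx("caffeine")
  f1 <- tempfile(fileext = ".sdf"); f2 <- tempfile(fileext = ".sdf")
  writeLines(paste0(write_molfile(caf, tweaked = FALSE), "\n$$$$"), f1)
  writeLines(paste0(write_molfile(caf, tweaked = TRUE), "\n$$$$"), f2)
  s1 <- read.SDFset(f1)[[1]]; s2 <- read.SDFset(f2)[[1]]
  a1 <- atomblock(s1); a2 <- atomblock(s2)
  expect_identical(rownames(a1), rownames(a2))          # elements
  expect_identical(a1[, 1:2], a2[, 1:2])                # coordinates
  b1 <- bondblock(s1); b2 <- bondblock(s2)
  expect_identical(b1[, 1:4], b2[, 1:4])                # bonds incl. stereo
})

test_that("SD files iterate records with their data fields", {
  mols <- lapply(c("benzene", "furan", "pyridine"), fx)
  sdf <- write_sdf(mols, fields = list(c(MW = "78.11"), c(MW = "68.07"),
                                       c(MW = "79.10", NAME = "pyridine")))
  recs <- read_sdf(sdf)
  expect_length(recs, 3)
  expect_equal(recs[[1]]$fields[["MW"]], "78.11")
  expect_equal(recs[[3]]$fields[["NAME"]], "pyridine")
  expect_equal(nrow(recs[[2]]$mol$atoms), 5)
  expect_length(read_sdf(""), 0)
  # missing terminator names the record ordinal
  broken <- sub("\\$\\$\\$\\$\\n$", "", sdf)
  expect_error(read_sdf(broken), "record 3")
  # tolerant mode skips a corrupt record with a warning
  lines <- strsplit(sdf, "\n")[[1]]
  lines[5] <- "garbage counts line"
  expect_warning(recs2 <- read_sdf(lines, tolerant = TRUE), "record 1")
  expect_length(recs2, 2)
})

test_that("RXN files partition molecules and capture atom maps", {
  rx <- builtin_reactions()
  imine <- parse_rxnfile(rx[["imine_formation"]])
  expect_length(imine$reactants, 2)
  expect_length(imine$products, 2)
  expect_gt(nrow(imine$atom_maps), 0)
  # every map class appears on both sides
  for (cl in unique(imine$atom_maps$class)) {
    sides <- imine$atom_maps$side[imine$atom_maps$class == cl]
    expect_setequal(unique(sides), c("reactant", "product"))
  }
  # unmapped 1+1 reaction: empty atom map table
  plain <- structure(list(reactants = list(fx("methylamine")),
                          products = list(fx("methanol"))),
                     class = "reaction")
  rt <- parse_rxnfile(write_rxnfile(plain))
  expect_equal(nrow(rt$atom_maps), 0)
  expect_error(parse_rxnfile("not a rxn"), "RXN")
  # declared counts must match the embedded molfiles
  lines <- strsplit(rx[["imine_formation"]], "\n")[[1]]
  lines[5] <- "  3  2"
  expect_error(parse_rxnfile(lines), "counts")
})

test_that("RD records expose the embedded reaction and DTYPE/DATUM fields", {
  rx <- builtin_reactions()[["urea_formation"]]
  rd <- paste(c("$RDFILE 1", "$RFMT", strsplit(rx, "\n")[[1]],
                "$DTYPE yield", "$DATUM 83"), collapse = "\n")
  recs <- read_rdfile(rd)
  expect_length(recs, 1)
  expect_length(recs[[1]]$rxn$reactants, 2)
  expect_equal(unname(recs[[1]]$fields["yield"]), "83")
})
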