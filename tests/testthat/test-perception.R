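test_that("ring perception lists the set of all rings", {
  expect_equal(vapply(fx("benzene")$rings, length, integer(1)), 6L)
  # naphthalene: two 6-cycles plus the 10-cycle perimeter
  np <- perceive_rings(parse_molfile(builtin_molecules()[["naphthalene"]]))
  expect_equal(np$method, "SAR")
  expect_equal(sort(vapply(np$rings, length, integer(1))), c(6L, 6L, 10L))
  # anthracene (cross-checked against an exhaustive cycle enumeration):
  # three 6-cycles, two 10-cycles, one 14-cycle
  an <- perceive_rings(parse_molfile(builtin_molecules()[["anthracene"]]))
  expect_equal(sort(vapply(an$rings, length, integer(1))),
               c(6L, 6L, 6L, 10L, 10L, 14L))
  # acyclic input gives an empty set, no error
  expect_length(perceive_rings(parse_molfile(builtin_molecules()[["propane"]]))$rings, 0)
})

test_that("condensed systems over the ring budget fall back to an SSSR basis", {
  cub <- parse_molfile(builtin_molecules()[["cubane"]])
  sar <- perceive_rings(cub)
  expect_equal(sar$method, "SAR")
  expect_equal(length(sar$rings), 28)  # 6 faces + 16 six-cycles + 6 eight-cycles
  fb <- perceive_rings(cub, ring_budget = 6)
  expect_equal(fb$method, "fallback")
  # SSSR basis size equals the cyclomatic number: 12 - 8 + 1 = 5
  expect_equal(length(fb$rings), 5)
  expect_true(all(vapply(fb$rings, length, integer(1)) == 4))
  # every fallback ring appears (as an atom set) in the SAR
  sar_keys <- vapply(sar$rings, function(r) paste(sort(r), collapse = ","),
                     character(1))
  fb_keys <- vapply(fb$rings, function(r) paste(sort(r), collapse = ","),
                    character(1))
  expect_true(all(fb_keys %in% sar_keys))
})

test_that("the aromaticity truth table holds", {
  aromatic_all <- function(nm) {
    p <- fx(nm)
    all(p$atoms$aromatic[vapply(seq_len(nrow(p$atoms)), function(a)
      any(vapply(p$rings, function(r) a %in% r, logical(1))), logical(1))])
  }
  for (nm in c("furan", "tropylium", "cyclopentadienide",
               "pyridone_2", "pyridone_4", "benzene", "naphthalene",
               "pyridine", "pyrrole", "thiophene"))
    expect_true(aromatic_all(nm), label = nm)
  for (nm in c("cyclohexane", "cyclooctatetraene"))
    expect_false(any(fx(nm)$atoms$aromatic), label = nm)
})

test_that("aromaticity is invariant under the input Kekule structure", {
  a <- perceive(parse_molfile(builtin_molecules()[["benzene_kekule_a"]]))
  b <- perceive(parse_molfile(builtin_molecules()[["benzene_kekule_b"]]))
  expect_identical(a$atoms$aromatic, b$atoms$aromatic)
  expect_identical(a$bonds$aromatic, b$bonds$aromatic)
  expect_identical(a$atoms$subtype, b$atoms$subtype)
})

test_that("perception is idempotent", {
  p1 <- perceive(parse_molfile(builtin_molecules()[["diazepam"]]))
  p2 <- perceive(p1)
  expect_identical(p1$atoms, p2$atoms)
  expect_identical(p1$bonds, p2$bonds)
  expect_identical(p1$rings, p2$rings)
  p3 <- perceive(perceive_aromaticity(p1))
  expect_identical(p1$atoms$aromatic, p3$atoms$aromatic)
})

test_that("the tweaked-file shortcut reproduces full perception exactly", {
  for (nm in c("benzene", "furan", "pyridone_2", "tropylium", "caffeine",
               "diazepam", "ellipticine", "naphthalene", "cyclohexane",
               "nag_glycoside", "sulfanilamide")) {
    full <- fx(nm)
    short <- perceive(parse_molfile(write_molfile(full, tweaked = TRUE)))
    expect_identical(short$atoms$aromatic, full$atoms$aromatic, info = nm)
    expect_identical(short$bonds$aromatic, full$bonds$aromatic, info = nm)
    expect_identical(short$atoms$subtype, full$atoms$subtype, info = nm)
  }
})

test_that("hybridization subtypes follow bond orders and aromaticity", {
  ea <- fx("ethyl_acetate")   # CH3-C(=O)-O-CH2-CH3
  expect_equal(ea$atoms$subtype[ea$atoms$element == "C"][2], "sp2") # carbonyl
  expect_equal(ea$atoms$subtype[4], "sp3")                          # ester O
  expect_true(all(fx("benzene")$atoms$subtype == "ar"))
  expect_true(all(fx("hcn")$atoms$subtype == "sp"))
  expect_true(all(fx("cyclohexane")$atoms$subtype == "sp3"))
})

test_that("implicit hydrogens come from charge-adjusted standard valences", {
  expect_equal(fx("methane")$atoms$total_h, 4L)
  w <- fx("water"); expect_equal(w$atoms$total_h, 2L)
  # pyrrole N-H survives aromatic perception
  py <- fx("pyrrole")
  expect_equal(py$atoms$total_h[py$atoms$element == "N"], 1L)
  # tropylium CH+ keeps one hydrogen (charge-reduced valence)
  tr <- fx("tropylium")
  expect_equal(unique(tr$atoms$total_h), 1L)
  # cyclopentadienide carbanion likewise
  cp <- fx("cyclopentadienide")
  expect_equal(unique(cp$atoms$total_h), 1L)
  expect_equal(sum(fx("caffeine")$atoms$total_h), 10L)  # C8H10N4O2
})

test_that("perception flags impossible valences as warnings, not errors", {
  txt <- paste(c("", "  t", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.0000    0.0000    0.0000 F   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  3  0  0  0  0",   # triple bond to fluorine
    "M  END"), collapse = "\n")
  p <- perceive(parse_molfile(txt))
  expect_true(p$perceived)
  expect_true(any(grepl("valence", p$warnings)))
})
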