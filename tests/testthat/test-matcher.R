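test_that("morgan ranks separate atoms by extended connectivity", {
  expect_length(unique(morgan_ranks(fx("benzene"))), 1)
  pr <- morgan_ranks(fx("propane"))
  expect_equal(pr[1], pr[3])
  expect_false(pr[1] == pr[2])
  expect_length(unique(morgan_ranks(fx("ethanol"))), 3)
})

test_that("reference atom selection favours branching and heteroatom contacts", {
  tol <- fx("toluene")           # CH3 then ring; ring carbon 2 bears the methyl
  expect_equal(select_reference_atom(tol, "heuristic"), 2L)
  ea <- fx("ethyl_acetate")      # carbonyl carbon has two oxygen neighbours
  expect_equal(select_reference_atom(ea, "heuristic"), 2L)
  one <- perceive(parse_molfile(builtin_molecules()[["methane"]]))
  expect_equal(select_reference_atom(one), 1L)
  # morgan mode returns an atom of the rarest rank
  m <- select_reference_atom(tol, "morgan")
  r <- morgan_ranks(tol)
  expect_equal(sum(r == r[m]), min(table(r)))
  expect_error(select_reference_atom(
    structure(list(atoms = fx("methane")$atoms[0, ],
                   bonds = fx("methane")$bonds[0, ], perceived = TRUE),
              class = "molecule")), "empty")
})

test_that("substructure and exact verdicts behave on named fixtures", {
  expect_true(match_mol(fx("benzene"), fx("toluene"))$verdict)
  expect_false(match_mol(fx("toluene"), fx("benzene"))$verdict)
  expect_true(match_mol(fx("caffeine"), fx("caffeine"), mode = "exact")$verdict)
  expect_false(match_mol(fx("caffeine"), fx("theophylline"),
                         mode = "exact")$verdict)
  expect_true(match_mol(fx("furan"), fx("benzofuran"))$verdict)
  expect_false(match_mol(fx("pyridine"), fx("benzene"))$verdict)
  expect_error(match_mol(parse_molfile(builtin_molecules()[["benzene"]]),
                         fx("benzene")), "perceived")
})

test_that("strict mode additionally requires matching subtypes", {
  # propane C-C-C maps into butane-like sp3 chains but not into benzene
  # even non-strict (aromaticity differs); strict rejects sp3-vs-sp2 cases
  ethanol <- fx("ethanol")
  tyr <- fx("tyrosine")
  expect_true(match_mol(fx("propane"), fx("tyrosine"))$verdict)
  # ethanol's C-C-O is all sp3; the only C-C-O path in tyrosine runs through
  # the sp2 acid carbon, so strict mode rejects what standard mode accepts
  expect_true(match_mol(ethanol, tyr, strict = FALSE)$verdict)
  expect_false(match_mol(ethanol, tyr, strict = TRUE)$verdict)
})

test_that("explicit needle hydrogens constrain the matched atom's hydrogen count", {
  # phenol with explicit O-H must not match anisole-like etherified oxygens
  ph <- fx("phenol")
  add_h <- function(mol, host) {
    mol$atoms <- rbind(mol$atoms[, 1:9],
                       data.frame(element = "H", charge = 0L, isotope = 0L,
                                  radical = 0L, x = 0, y = 0, z = 0, map = 0L,
                                  aromatic = FALSE, stringsAsFactors = FALSE))
    mol$bonds <- rbind(mol$bonds[, c("a1", "a2", "order", "stereo")],
                       data.frame(a1 = host, a2 = nrow(mol$atoms),
                                  order = 1L, stereo = 0L))
    mol$bonds$aromatic <- FALSE
    mol$perceived <- FALSE
    perceive(mol)
  }
  ph_h <- add_h(parse_molfile(builtin_molecules()[["phenol"]]), 1L)  # O-H explicit
  expect_true(match_mol(ph_h, fx("tyrosine"))$verdict)
  # methylate the phenol oxygen of a copy of tyrosine: no O-H left
  tyr_ome <- decorate_molecule(parse_molfile(builtin_molecules()[["tyrosine"]]), 0, 1)
  o_idx <- which(tyr_ome$atoms$element == "O" & tyr_ome$atoms$heavy_degree == 1 &
                   tyr_ome$atoms$total_h == 1)[1]
  tyr_ome$atoms <- rbind(tyr_ome$atoms[, 1:9],
                         data.frame(element = "C", charge = 0L, isotope = 0L,
                                    radical = 0L, x = 0, y = 0, z = 0, map = 0L,
                                    aromatic = FALSE, stringsAsFactors = FALSE))
  tyr_ome$bonds <- rbind(tyr_ome$bonds[, c("a1", "a2", "order", "stereo")],
                         data.frame(a1 = o_idx, a2 = nrow(tyr_ome$atoms),
                                    order = 1L, stereo = 0L))
  tyr_ome$bonds$aromatic <- FALSE
  tyr_ome$perceived <- FALSE
  tyr_ome <- perceive(tyr_ome)
  expect_false(match_mol(ph_h, tyr_ome)$verdict)
  expect_true(match_mol(ph, tyr_ome)$verdict)  # without explicit H it matches
})

test_that("E/Z geometry and R/S parity are enforced only when requested", {
  e2 <- fx("e_2_butene"); z2 <- fx("z_2_butene")
  expect_true(match_mol(e2, z2)$verdict)
  expect_false(match_mol(e2, z2, check_geometry = TRUE)$verdict)
  expect_true(match_mol(e2, e2, check_geometry = TRUE)$verdict)
  expect_true(match_mol(z2, z2, check_geometry = TRUE)$verdict)
  # wedge-annotated 2D enantiomer vs. true-3D forms
  r2d <- fx("chfclbr_r_2d")
  expect_true(match_mol(r2d, fx("chfclbr_r_3d"), check_chirality = TRUE)$verdict)
  expect_false(match_mol(r2d, fx("chfclbr_s_3d"), check_chirality = TRUE)$verdict)
  expect_true(match_mol(r2d, fx("chfclbr_s_3d"))$verdict)
  expect_false(match_mol(fx("chfclbr_s_2d"), fx("chfclbr_r_3d"),
                         check_chirality = TRUE)$verdict)
  expect_true(match_mol(fx("chfclbr_r_3d"), fx("chfclbr_r_3d"),
                        check_chirality = TRUE, mode = "exact")$verdict)
})

test_that("mapping enumeration counts embeddings (global match matrix mode)", {
  maps <- enumerate_mappings(fx("benzene"), fx("benzene"))
  expect_length(maps, 12)   # dihedral automorphisms of the 6-ring
  expect_true(all(vapply(maps, function(m) !anyDuplicated(m), logical(1))))
  expect_length(enumerate_mappings(fx("ethane"), fx("methane")), 0)
  first <- enumerate_mappings(fx("phenol"), fx("tyrosine"), which = "first")
  expect_length(first, 1)
  m <- first[[1]]
  ph <- fx("phenol"); tyr <- fx("tyrosine")
  expect_true(all(ph$atoms$element == tyr$atoms$element[m]))
})

test_that("exact match is an equivalence relation on fixtures", {
  a <- perceive(parse_molfile(builtin_molecules()[["benzene_kekule_a"]]))
  b <- perceive(parse_molfile(builtin_molecules()[["benzene_kekule_b"]]))
  expect_true(match_mol(a, a, mode = "exact")$verdict)          # reflexive
  expect_true(match_mol(a, b, mode = "exact")$verdict)          # symmetric pair
  expect_true(match_mol(b, a, mode = "exact")$verdict)
  tw <- perceive(parse_molfile(write_molfile(fx("caffeine"), tweaked = TRUE)))
  expect_true(match_mol(fx("caffeine"), tw, mode = "exact")$verdict)
  expect_true(match_mol(tw, fx("caffeine"), mode = "exact")$verdict)
})

test_that("substructure matching is transitive on fixture chains", {
  expect_true(match_mol(fx("benzene"), fx("naphthalene"))$verdict)
  expect_true(match_mol(fx("naphthalene"), fx("anthracene"))$verdict)
  expect_true(match_mol(fx("benzene"), fx("anthracene"))$verdict)
  expect_true(match_mol(fx("pyridine"), fx("quinoline"))$verdict)
  expect_true(match_mol(fx("quinoline"), fx("quinoline"))$verdict)
})

test_that("match results are identical for fresh and tweak-loaded haystacks", {
  for (nm in c("toluene", "caffeine", "diazepam", "nag_glycoside")) {
    fresh <- fx(nm)
    loaded <- perceive(parse_molfile(write_molfile(fresh, tweaked = TRUE)))
    for (qn in c("benzene", "furan", "methylamine", "ethyl_acetate")) {
      q <- fx(qn)
      expect_equal(match_mol(q, loaded)$verdict, match_mol(q, fresh)$verdict,
                   info = paste(qn, "in", nm))
    }
  }
})

test_that("verdicts agree with the brute-force oracle on seeded random pairs", {
  n_true <- 0
  for (i in 1:400) {
    hay <- perceive(generate_molecule(20000 + i, n_atoms = c(8, 14)))
    needle <- if (i %% 2 == 0)
      extract_needle(hay, n_drop = 1 + (i %% 6), seed = 21000 + i)
    else perceive(generate_molecule(23000 + i, n_atoms = c(3, 8)))
    v <- match_mol(needle, hay)$verdict
    expect_equal(v, oracle_subiso(needle, hay), info = paste("pair", i))
    if (v) n_true <- n_true + 1
  }
  expect_gt(n_true, 100)  # both verdicts are exercised
})
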