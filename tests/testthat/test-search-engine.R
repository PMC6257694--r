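small_dict <- function() lapply(c("benzene", "pyridine", "furan"), fx)

test_that("indexing stores recomputable descriptors with the tweaked molfile", {
  idx <- mol_index(dictionary = small_dict())
  rec <- index_structure(idx, builtin_molecules()[["ethyl_acetate"]], id = "ea")
  reg <- fg_registry()
  ester_pos <- reg$position[reg$id == "ester"]
  expect_true(bs_get(rec$fg, ester_pos))
  expect_error(index_structure(idx, builtin_molecules()[["benzene"]], id = "ea"),
               "duplicate")
  rec2 <- index_structure(idx, builtin_molecules()[["benzene"]], id = "bz")
  expect_equal(bs_segments(rec2$dict)[1] %% 2, 1)  # identity flag: odd
  # stored-descriptor integrity: recompute everything from the stored
  # tweaked molfile and compare bit-exactly
  for (rec in idx$compounds) {
    mol <- perceive(parse_molfile(rec$molfile))
    expect_identical(bs_segments(hashed_fingerprint(mol)), rec$fp_segments)
    expect_identical(detect_groups(mol)$segments, rec$fg_segments)
    expect_identical(bs_segments(dictionary_fingerprint(mol, idx$dictionary)),
                     rec$dict_segments)
    expect_identical(unname(compute_molstat(mol)), unname(rec$molstat))
  }
})

test_that("reaction records store cumulative OR fingerprints and no molstat", {
  idx <- mol_index(dictionary = small_dict())
  rx <- builtin_reactions()
  rec <- index_reaction(idx, rx[["imine_formation"]], id = "imine")
  reg <- fg_registry()
  imine_pos <- reg$position[reg$id == "imine"]
  expect_true(bs_get(rec$products$fg, imine_pos))
  expect_false(bs_get(rec$reactants$fg, imine_pos))
  expect_null(rec$molstat)
  # cumulative OR law
  member_or <- Reduce(function(a, b) {
    structure(unclass(a) | unclass(b), class = "bitstring")
  }, lapply(rec$reactants$mols, hashed_fingerprint))
  expect_identical(member_or, rec$reactants$fp)
  # one-reactant side: cumulative equals the member fingerprint
  rec2 <- index_reaction(idx, rx[["urea_formation"]], id = "urea")
  expect_identical(rec2$products$fp,
                   hashed_fingerprint(rec2$products$mols[[1]]))
  # reactions need both sides
  half <- structure(list(reactants = list(), products = list(fx("water"))),
                    class = "reaction")
  expect_error(index_reaction(idx, half, id = "bad"), "at least one")
})

test_that("substructure search reproduces brute-force matching", {
  idx <- mol_index(dictionary = small_dict())
  mols <- lapply(1:60, function(s)
    perceive(generate_molecule(30000 + s, n_atoms = c(8, 18))))
  for (s in seq_along(mols))
    index_structure(idx, mols[[s]], id = sprintf("m%02d", s))
  index_structure(idx, builtin_molecules()[["caffeine"]], id = "caffeine")
  index_structure(idx, builtin_molecules()[["theophylline"]], id = "theophylline")

  # the indexed fixture finds itself in exact mode
  res <- substructure_search(idx, builtin_molecules()[["caffeine"]],
                             mode = "exact")
  expect_true("caffeine" %in% res$hits)
  expect_false("theophylline" %in% res$hits)

  # caffeine as substructure query: theophylline lacks one N-methyl
  res2 <- substructure_search(idx, builtin_molecules()[["caffeine"]])
  expect_true("caffeine" %in% res2$hits)
  expect_false("theophylline" %in% res2$hits)
  expect_gte(res2$n_candidates, length(res2$hits))

  # theophylline core is contained in caffeine
  res3 <- substructure_search(idx, builtin_molecules()[["theophylline"]])
  expect_true(all(c("caffeine", "theophylline") %in% res3$hits))

  # equality with brute force over the whole index for assorted queries
  queries <- c(lapply(c(5, 12, 23), function(i)
    extract_needle(mols[[i]], n_drop = 4, seed = 31000 + i)),
    lapply(c(1, 2), function(i)
      perceive(generate_molecule(32000 + i, n_atoms = c(4, 8)))))
  for (q in queries) {
    got <- substructure_search(idx, q)
    brute <- names(idx$compounds)[vapply(idx$compounds, function(r)
      match_mol(q, r$mol)$verdict, logical(1))]
    expect_setequal(got$hits, brute)
    expect_gte(got$n_candidates, length(brute))
  }
})

test_that("a dictionary-identical query answers from bits alone", {
  idx <- mol_index(dictionary = small_dict())
  for (nm in c("toluene", "quinoline", "cyclohexane", "benzofuran", "furan"))
    index_structure(idx, builtin_molecules()[[nm]], id = nm)
  res <- substructure_search(idx, builtin_molecules()[["benzene"]])
  expect_true(res$fast_path)
  expect_setequal(res$hits, c("toluene", "quinoline", "benzofuran"))
  res2 <- substructure_search(idx, builtin_molecules()[["furan"]])
  expect_true(res2$fast_path)
  expect_setequal(res2$hits, c("benzofuran", "furan"))
})

test_that("similarity search ranks by Tanimoto with sound pre-filters", {
  idx <- mol_index(dictionary = list())
  mols <- lapply(1:40, function(s)
    perceive(generate_molecule(33000 + s, n_atoms = c(8, 16))))
  for (s in seq_along(mols))
    index_structure(idx, mols[[s]], id = sprintf("m%02d", s))
  q <- mols[[7]]
  res <- similarity_search(idx, q, min_score = 0)
  expect_equal(res$id[1], "m07")
  expect_equal(res$score[1], 1)
  # identical to exhaustive pairwise Tanimoto
  qfp <- hashed_fingerprint(q)
  exhaustive <- vapply(idx$compounds, function(r) tanimoto(qfp, r$fp),
                       numeric(1))
  expect_equal(nrow(res), length(exhaustive))
  expect_equal(res$score,
               unname(sort(exhaustive, decreasing = TRUE)))
  # thresholded search never loses a qualifying record
  for (t in c(0.2, 0.4, 0.6)) {
    rt <- similarity_search(idx, q, min_score = t)
    expect_setequal(rt$id, names(exhaustive)[exhaustive >= t])
  }
  # the popcount bound itself: T(a,b) <= min(p)/max(p)
  for (r in idx$compounds) {
    p1 <- bs_popcount(qfp); p2 <- r$popcount
    expect_lte(tanimoto(qfp, r$fp), min(p1, p2) / max(p1, p2) + 1e-12)
  }
  expect_error(similarity_search(idx, q, min_score = 2), "min_score")
})

test_that("functional-group search equals descriptor filtering, superset of substructure", {
  idx <- mol_index(dictionary = small_dict())
  # analog series around sulfanilamide plus background molecules
  base <- parse_molfile(builtin_molecules()[["sulfanilamide"]])
  for (k in 1:12)
    index_structure(idx, decorate_molecule(base, k %% 4, seed = 500 + k),
                    id = sprintf("sa%02d", k))
  for (s in 1:25)
    index_structure(idx, generate_molecule(34000 + s, n_atoms = c(8, 16)),
                    id = sprintf("bg%02d", s))
  hits <- functional_group_search(idx, c("primary aromatic amine", "sulfonamide"))
  expect_true("sa01" %in% hits)
  # equality with direct mask evaluation over all records
  preds <- mask_predicates(encode_group_query(
    fg_positions(c("primary aromatic amine", "sulfonamide"))))
  brute <- names(idx$compounds)[vapply(idx$compounds, function(r)
    satisfies_masks(r$fg_segments, preds), logical(1))]
  expect_setequal(hits, brute)
  # group hits are a superset of the substructure hits when the query pins
  # the arylamino group down with explicit hydrogens (without them, a
  # substituted aniline nitrogen would still match the substructure query
  # while no longer being a primary aromatic amine)
  q <- parse_molfile(builtin_molecules()[["sulfanilamide"]])
  for (h in 1:2) {
    q$atoms <- rbind(q$atoms[, 1:9],
                     data.frame(element = "H", charge = 0L, isotope = 0L,
                                radical = 0L, x = 0, y = 0, z = 0, map = 0L,
                                aromatic = FALSE, stringsAsFactors = FALSE))
    q$bonds <- rbind(q$bonds[, c("a1", "a2", "order", "stereo")],
                     data.frame(a1 = 1L, a2 = nrow(q$atoms), order = 1L,
                                stereo = 0L))
    q$bonds$aromatic <- FALSE
  }
  sub <- substructure_search(idx, perceive(q))
  expect_gt(length(sub$hits), 0)
  expect_true(all(sub$hits %in% hits))
  # empty selection matches every record
  expect_length(functional_group_search(idx, integer(0)),
                length(idx$compounds))
})

test_that("reaction search verifies both sides, maps, and half reactions", {
  idx <- mol_index(dictionary = small_dict())
  rx <- builtin_reactions()
  for (nm in names(rx)) index_reaction(idx, rx[[nm]], id = nm)
  res <- reaction_search(idx, rx[["imine_formation"]])
  expect_equal(res$hits, "imine_formation")
  expect_true(reaction_search(idx, rx[["imine_formation"]],
                              check_maps = TRUE)$hits == "imine_formation")
  # half reaction: query only the product side of the urea formation
  pr <- parse_rxnfile(rx[["urea_formation"]])
  half <- structure(list(reactants = list(), products = pr$products,
                         atom_maps = pr$atom_maps[0, ]), class = "reaction")
  expect_equal(reaction_search(idx, half)$hits, "urea_formation")
  # brute force equality: stage 2 applied to every record
  for (nm in names(rx)) {
    q <- parse_rxnfile(rx[[nm]])
    got <- reaction_search(idx, q)$hits
    brute <- names(idx$reactions)[vapply(idx$reactions, function(r) {
      all(vapply(q$reactants, function(m) any(vapply(r$reactants$mols,
        function(c) match_mol(perceive(m), c)$verdict, logical(1))), logical(1))) &&
      all(vapply(q$products, function(m) any(vapply(r$products$mols,
        function(c) match_mol(perceive(m), c)$verdict, logical(1))), logical(1)))
    }, logical(1))]
    expect_setequal(got, brute)
  }
})

test_that("reaction functional-group modes follow the cumulative bit semantics", {
  idx <- mol_index(dictionary = small_dict())
  rx <- builtin_reactions()
  for (nm in names(rx)) index_reaction(idx, rx[[nm]], id = nm)
  expect_equal(reaction_fg_search(idx, "imine", "created"), "imine_formation")
  expect_length(reaction_fg_search(idx, "imine", "lost"), 0)
  expect_equal(reaction_fg_search(idx, "isocyanate", "lost"), "urea_formation")
  expect_equal(reaction_fg_search(idx, "carboxylic acid hydrazide", "created"),
               "hydrazide_formation")
  expect_equal(reaction_fg_search(idx, "ester", "lost"), "hydrazide_formation")
  expect_true("imine_formation" %in% reaction_fg_search(idx, "amine", "in_reactants"))
  expect_true("urea_formation" %in% reaction_fg_search(idx, "urea", "in_products"))
})

test_that("hit lists format as delimited text", {
  expect_equal(format_hitlist(c("a", "b")), "a\tT\nb\tT")
  expect_equal(format_hitlist(character(0)), "")
  expect_match(format_hitlist("x", scores = 0.5), "x\t0.5000")
})
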