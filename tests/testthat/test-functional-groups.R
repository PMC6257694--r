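test_that("the registry is frozen, unique, and covers the required groups", {
  reg <- fg_registry()
  expect_gte(nrow(reg), 64)
  expect_false(anyDuplicated(reg$position) > 0)
  expect_false(anyDuplicated(reg$name) > 0)
  required <- c("ester", "acid chloride", "amide", "secondary carboxamide",
                "tertiary carboxamide", "lactam", "amidine", "amine",
                "primary aromatic amine", "hydrazine", "hydroxylamine",
                "imide", "sulfonamide", "alcohol", "primary alcohol",
                "secondary alcohol", "acetal", "imine", "aryl chloride",
                "isocyanate", "carboxylic acid hydrazide", "heterocycle",
                "aromatic", "nitro", "nitrile", "ether", "thiol",
                "thioether", "aldehyde", "ketone", "carboxylic acid",
                "anhydride", "urea", "carbamate", "phenol", "enol",
                "azide", "diazo", "sulfone", "sulfoxide", "phosphate")
  expect_true(all(required %in% reg$name))
  expect_true(all(reg$position >= 0 & reg$position < 256))
})

test_that("ethyl acetate is an ester and no other carboxyl derivative", {
  p <- detect_groups(fx("ethyl_acetate"))
  expect_true("ester" %in% p$ids)
  expect_false(any(c("amide", "acid_chloride", "amidine", "carboxylic_acid",
                     "anhydride") %in% p$ids))
})

test_that("known drug molecules give their expected group profiles", {
  s <- detect_groups(fx("sulfanilamide"))
  expect_true(all(c("primary aromatic amine", "sulfonamide") %in% s$names))
  d <- detect_groups(fx("diazepam"))
  expect_true(all(c("aromatic", "heterocycle", "imine", "tertiary carboxamide",
                    "lactam", "aryl chloride") %in% d$names))
  expect_false("amine" %in% d$names)
  g <- detect_groups(fx("nag_glycoside"))
  expect_true(all(c("heterocycle", "acetal", "secondary carboxamide",
                    "primary alcohol", "secondary alcohol") %in% g$names))
  expect_false("tertiary carboxamide" %in% g$names)
})

test_that("amine exclusion rules reject N-heteroatom and N-acyl nitrogens", {
  ph <- detect_groups(fx("phenylhydrazine"))
  expect_true("hydrazine" %in% ph$ids)
  expect_false("amine" %in% ph$ids)
  # amide nitrogens are never amines
  for (nm in c("diazepam", "nag_glycoside", "caffeine", "dimethylurea",
               "acetohydrazide")) {
    p <- detect_groups(fx(nm))
    expect_false("amine" %in% p$ids, label = nm)
  }
  # but an actual amine is one
  expect_true("amine" %in% detect_groups(fx("methylamine"))$ids)
  expect_true("primary_aliphatic_amine" %in% detect_groups(fx("methylamine"))$ids)
})

test_that("more group chemistry: acids, ureas, isocyanates, hydrazides", {
  expect_true("carboxylic acid" %in% detect_groups(fx("tyrosine"))$names)
  expect_true("phenol" %in% detect_groups(fx("tyrosine"))$names)
  expect_true("urea" %in% detect_groups(fx("dimethylurea"))$names)
  expect_true("isocyanate" %in% detect_groups(fx("methyl_isocyanate"))$names)
  expect_true("carboxylic acid hydrazide" %in%
                detect_groups(fx("acetohydrazide"))$names)
  expect_true("imine" %in% detect_groups(fx("methanimine_n_methyl"))$names)
  expect_true("ester" %in% detect_groups(fx("methyl_acetate"))$names)
  expect_true("lactam" %in% detect_groups(fx("caffeine"))$names)
  expect_true("alcohol" %in% detect_groups(fx("ethanol"))$names)
})

test_that("descriptor bits, names and segments stay consistent", {
  reg <- fg_registry()
  for (nm in c("sulfanilamide", "diazepam", "nag_glycoside", "caffeine")) {
    p <- detect_groups(fx(nm))
    expect_identical(p$names, reg$name[match(p$positions, reg$position)],
                     info = nm)
    expect_identical(p$segments, bs_segments(p$descriptor), info = nm)
    expect_setequal(which(as.logical(p$descriptor)) - 1, p$positions)
  }
})

test_that("query encoding reproduces the worked 32-bit segment example", {
  expect_equal(encode_group_query(c(3, 33, 38)),
               c(8, 66, 0, 0, 0, 0, 0, 0))
  expect_equal(encode_group_query(integer(0)), rep(0, 8))
  expect_equal(encode_group_query(0), c(1, rep(0, 7)))
  expect_error(encode_group_query(256), "0..255")
  preds <- mask_predicates(encode_group_query(c(3, 33, 38)))
  expect_equal(preds$segment, c(1, 2))
  expect_equal(preds$mask, c(8, 66))
  expect_equal(nrow(mask_predicates(rep(0, 8))), 0)
  p2 <- mask_predicates(c(1, 0, 0, 0, 0, 0, 0, 1))
  expect_equal(p2$segment, c(1, 8))
  expect_equal(p2$mask, c(1, 1))
})

test_that("mask predicates implement monotone subset semantics", {
  for (nm in c("sulfanilamide", "diazepam", "ethyl_acetate")) {
    det <- detect_groups(fx(nm))
    # query with a subset of the detected positions: satisfied
    sub <- det$positions[seq_len(max(1, length(det$positions) - 1))]
    expect_true(satisfies_masks(det$segments,
                                mask_predicates(encode_group_query(sub))),
                info = nm)
    # adding one absent position breaks it
    absent <- setdiff(0:255, det$positions)[1]
    expect_false(satisfies_masks(det$segments,
                                 mask_predicates(encode_group_query(
                                   c(sub, absent)))), info = nm)
    # empty query matches everything
    expect_true(satisfies_masks(det$segments,
                                mask_predicates(encode_group_query(integer(0)))))
  }
})
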