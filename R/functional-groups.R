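#' @title Rule-based functional-group classification
#' @description
#' Walks the perceived atom and bond lists and dispatches on what it finds:
#' a C=X double bond triggers carboxyl-derivative discrimination (ester vs.
#' amide vs. acid chloride vs. amidine vs. acid vs. anhydride, by inspecting
#' the heteroatoms attached to the carbonyl carbon and their substituents),
#' nitrogen centres are classified with the amine exclusion rules (no
#' heteroatom and no acyl residue on the nitrogen), and so on.  Every
#' detected group sets one fixed bit of a 256-bit descriptor that is stored
#' and queried as eight unsigned 32-bit segments (`fg01` .. `fg08`).
#' @name functional_groups
NULL

.FG_TABLE <- local({
  e <- list(
    c("aromatic", "aromatic"),
    c("heterocycle", "heterocycle"),
    c("cation", "cation"),
    c("anion", "anion"),
    c("alkene", "alkene"),
    c("alkyne", "alkyne"),
    c("alcohol", "alcohol"),
    c("primary_alcohol", "primary alcohol"),
    c("secondary_alcohol", "secondary alcohol"),
    c("tertiary_alcohol", "tertiary alcohol"),
    c("phenol", "phenol"),
    c("enol", "enol"),
    c("ether", "ether"),
    c("acetal", "acetal"),
    c("hemiacetal", "hemiacetal"),
    c("aldehyde", "aldehyde"),
    c("ketone", "ketone"),
    c("carboxylic_acid", "carboxylic acid"),
    c("ester", "ester"),
    c("lactone", "lactone"),
    c("acid_chloride", "acid chloride"),
    c("acyl_halide", "acyl halide"),
    c("anhydride", "anhydride"),
    c("amide", "amide"),
    c("primary_carboxamide", "primary carboxamide"),
    c("secondary_carboxamide", "secondary carboxamide"),
    c("tertiary_carboxamide", "tertiary carboxamide"),
    c("lactam", "lactam"),
    c("imide", "imide"),
    c("urea", "urea"),
    c("carbamate", "carbamate"),
    c("amidine", "amidine"),
    c("guanidine", "guanidine"),
    c("carboxylic_acid_hydrazide", "carboxylic acid hydrazide"),
    c("amine", "amine"),
    c("primary_amine", "primary amine"),
    c("secondary_amine", "secondary amine"),
    c("tertiary_amine", "tertiary amine"),
    c("primary_aromatic_amine", "primary aromatic amine"),
    c("primary_aliphatic_amine", "primary aliphatic amine"),
    c("hydrazine", "hydrazine"),
    c("hydrazone", "hydrazone"),
    c("hydroxylamine", "hydroxylamine"),
    c("imine", "imine"),
    c("oxime", "oxime"),
    c("nitrile", "nitrile"),
    c("isocyanate", "isocyanate"),
    c("isothiocyanate", "isothiocyanate"),
    c("nitro", "nitro"),
    c("nitroso", "nitroso"),
    c("azide", "azide"),
    c("diazo", "diazo"),
    c("thiol", "thiol"),
    c("thioether", "thioether"),
    c("disulfide", "disulfide"),
    c("sulfoxide", "sulfoxide"),
    c("sulfone", "sulfone"),
    c("sulfonic_acid", "sulfonic acid"),
    c("sulfonate_ester", "sulfonate ester"),
    c("sulfonamide", "sulfonamide"),
    c("thioamide", "thioamide"),
    c("thiourea", "thiourea"),
    c("alkyl_fluoride", "alkyl fluoride"),
    c("alkyl_chloride", "alkyl chloride"),
    c("alkyl_bromide", "alkyl bromide"),
    c("alkyl_iodide", "alkyl iodide"),
    c("aryl_fluoride", "aryl fluoride"),
    c("aryl_chloride", "aryl chloride"),
    c("aryl_bromide", "aryl bromide"),
    c("aryl_iodide", "aryl iodide"),
    c("phosphate", "phosphate")
  )
  data.frame(position = seq_along(e) - 1L,
             id = vapply(e, `[`, character(1), 1),
             name = vapply(e, `[`, character(1), 2),
             stringsAsFactors = FALSE)
})

#' The functional-group registry
#'
#' One row per recognizable group: the fixed 0-based `position` of its bit
#' in the 256-bit descriptor, a stable `id`, and the English `name` used in
#' clear-text output.  The table is frozen at build time; positions never
#' move between releases.
#' @return a data frame with columns `position`, `id`, `name`.
#' @export
fg_registry <- function() .FG_TABLE

#' Look up registry positions for group ids or names
#' @param groups character vector of group ids or English names
#' @return integer vector of 0-based bit positions
#' @export
fg_positions <- function(groups) {
  reg <- fg_registry()
  idx <- match(groups, reg$id)
  idx[is.na(idx)] <- match(groups[is.na(idx)], reg$name)
  if (anyNA(idx))
    stop("unknown functional group(s): ",
         paste(groups[is.na(idx)], collapse = ", "))
  reg$position[idx]
}

#' Detect functional groups
#'
#' @param mol a perceived `molecule`
#' @return an object of class `fg_profile`: `descriptor` (a 256-bit
#'   [bitstring()]), `segments` (eight unsigned 32-bit doubles, fg01..fg08),
#'   `positions` (0-based set bits) and `names` (English clear-text names,
#'   in registry order).
#' @examples
#' mol <- perceive(parse_molfile(builtin_molecules()[["ethyl_acetate"]]))
#' detect_groups(mol)$names   # "ester"
#' @export
detect_groups <- function(mol) {
  stopifnot(mol$perceived)
  at <- mol$atoms; bd <- mol$bonds
  n <- nrow(at)
  adj <- adjacency_list(mol)
  lookup <- bond_lookup(mol)
  hit <- stats::setNames(logical(nrow(.FG_TABLE)), .FG_TABLE$id)
  set <- function(id) hit[id] <<- TRUE

  ordm <- function(a, b) bd$order[bond_index(lookup, n, a, b)]
  arom <- function(a, b) {
    bi <- bond_index(lookup, n, a, b)
    bd$aromatic[bi] || bd$order[bi] == 4
  }
  # sigma connections follow the input bond order even inside perceived
  # aromatic rings (the N-C single bonds of a pyridone-type lactam stay
  # visible); pi patterns (C=O, C=N, C=C) only count localized double
  # bonds, never bonds belonging to an aromatic ring
  sgl <- function(a, b) ordm(a, b) == 1
  dbl <- function(a, b) ordm(a, b) == 2 && !arom(a, b)
  heavy_nbrs <- lapply(seq_len(n), function(a)
    adj[[a]][!is_hydrogen(at$element[adj[[a]]])])
  el <- at$element
  dbl_nbrs <- lapply(seq_len(n), function(a)
    heavy_nbrs[[a]][vapply(heavy_nbrs[[a]], function(b) dbl(a, b), logical(1))])
  # acyl carbon: C doubly bonded to O or S (thiocarbonyl included)
  is_acyl <- vapply(seq_len(n), function(a)
    el[a] == "C" && any(el[dbl_nbrs[[a]]] %in% c("O", "S")), logical(1))
  is_sulfonyl <- vapply(seq_len(n), function(a)
    el[a] == "S" && sum(el[dbl_nbrs[[a]]] == "O") >= 2, logical(1))
  in_same_ring <- function(a, b)
    any(vapply(mol$rings, function(r) a %in% r && b %in% r, logical(1)))

  if (any(at$aromatic)) set("aromatic")
  if (any(vapply(mol$rings, function(r) any(el[r] != "C"), logical(1))))
    set("heterocycle")
  heavy <- !is_hydrogen(el)
  if (any(heavy & at$charge > 0)) set("cation")
  if (any(heavy & at$charge < 0)) set("anion")
  for (i in seq_len(nrow(bd))) {
    if (el[bd$a1[i]] == "C" && el[bd$a2[i]] == "C" && !bd$aromatic[i]) {
      if (bd$order[i] == 2) set("alkene")
      if (bd$order[i] == 3) set("alkyne")
    }
  }

  for (a in seq_len(n)) {
    ea <- el[a]
    nb <- heavy_nbrs[[a]]

    if (ea == "O" && at$charge[a] == 0) {
      csingle <- nb[el[nb] == "C" & vapply(nb, function(b) sgl(a, b), logical(1))]
      if (at$total_h[a] >= 1 && length(nb) == 1 && length(csingle) == 1) {
        c1 <- csingle[1]
        if (!is_acyl[c1] && !is_sulfonyl[c1]) {
          if (at$aromatic[c1]) set("phenol")
          else if (any(el[dbl_nbrs[[c1]]] == "C")) set("enol")
          else if (at$subtype[c1] == "sp3") {
            other_het <- setdiff(heavy_nbrs[[c1]], a)
            other_het <- other_het[is_heteroatom(el[other_het])]
            if (!length(other_het)) {
              set("alcohol")
              ncn <- sum(el[heavy_nbrs[[c1]]] == "C")
              if (ncn <= 1) set("primary_alcohol")
              else if (ncn == 2) set("secondary_alcohol")
              else set("tertiary_alcohol")
            }
          }
        }
      }
      if (length(csingle) == 2 && at$total_h[a] == 0 && !at$aromatic[a] &&
          !any(is_acyl[csingle]) && !any(is_sulfonyl[csingle]))
        set("ether")
    }

    if (ea == "C") {
      # acetal / hemiacetal centre: sp3 carbon with two single-bonded oxygens
      if (at$subtype[a] == "sp3") {
        osingle <- nb[el[nb] == "O" &
                      vapply(nb, function(b) sgl(a, b), logical(1))]
        if (length(osingle) == 2) {
          o_r <- vapply(osingle, function(o)
            sum(el[heavy_nbrs[[o]]] == "C") == 2, logical(1))
          o_h <- vapply(osingle, function(o)
            at$total_h[o] >= 1 && length(heavy_nbrs[[o]]) == 1, logical(1))
          others <- setdiff(nb, osingle)
          if (all(el[others] == "C")) {
            if (all(o_r)) set("acetal")
            else if (sum(o_r) == 1 && sum(o_h) == 1) set("hemiacetal")
          }
        }
      }
      dO <- dbl_nbrs[[a]][el[dbl_nbrs[[a]]] == "O"]
      dN <- dbl_nbrs[[a]][el[dbl_nbrs[[a]]] == "N"]
      dS <- dbl_nbrs[[a]][el[dbl_nbrs[[a]]] == "S"]
      sing <- nb[vapply(nb, function(b) sgl(a, b), logical(1))]
      shet <- sing[is_heteroatom(el[sing])]

      if (length(dO) == 1 && length(dN) == 1) set("isocyanate")
      if (length(dS) == 1 && length(dN) == 1) set("isothiocyanate")

      if (length(dO) == 1 && length(dN) == 0 && length(dS) == 0) {
        # carbonyl carbon: dispatch on the attached heteroatoms
        sC <- sing[el[sing] == "C"]
        if (!length(shet)) {
          if (length(sC) <= 1 && at$total_h[a] >= 1) set("aldehyde")
          else if (length(sC) == 2) set("ketone")
        }
        hal <- shet[el[shet] %in% .HALOGENS]
        if (length(hal)) {
          set("acyl_halide")
          if (any(el[hal] == "Cl")) set("acid_chloride")
        }
        sO <- shet[el[shet] == "O"]
        sN <- shet[el[shet] == "N"]
        for (o in sO) {
          if (at$total_h[o] >= 1 && length(heavy_nbrs[[o]]) == 1) {
            set("carboxylic_acid")
          } else {
            oc <- setdiff(heavy_nbrs[[o]], a)
            oc <- oc[el[oc] == "C"]
            if (length(oc)) {
              if (any(is_acyl[oc])) set("anhydride")
              else if (length(sN)) set("carbamate")
              else {
                set("ester")
                if (in_same_ring(a, o)) set("lactone")
              }
            }
          }
        }
        if (length(sN)) {
          set("amide")
          if (length(sN) >= 2) set("urea")
          for (nn in sN) {
            if (in_same_ring(a, nn)) set("lactam")
            others <- setdiff(heavy_nbrs[[nn]], a)
            if (any(el[others] == "N")) { set("carboxylic_acid_hydrazide"); next }
            if (sum(is_acyl[others]) >= 1) { set("imide"); next }
            if (any(is_heteroatom(el[others]))) next
            nC <- sum(el[others] == "C")
            if (nC == 0) set("primary_carboxamide")
            else if (nC == 1) set("secondary_carboxamide")
            else set("tertiary_carboxamide")
          }
        }
      }

      if (length(dN) == 1 && length(dO) == 0 && length(dS) == 0) {
        nn <- dN[1]
        sN <- sing[el[sing] == "N"]
        n_others <- setdiff(heavy_nbrs[[nn]], a)
        if (length(sN)) {
          set("amidine")
          if (length(sN) >= 2) set("guanidine")
        } else if (all(el[setdiff(nb, nn)] == "C")) {
          if (any(el[n_others] == "N")) set("hydrazone")
          else if (any(el[n_others] == "O" &
                       vapply(n_others, function(o)
                         at$total_h[o] >= 1, logical(1)))) set("oxime")
          else if (all(el[n_others] == "C")) set("imine")
        }
      }

      if (any(vapply(nb, function(b)
        el[b] == "N" && ordm(a, b) == 3, logical(1)))) {
        trip <- nb[el[nb] == "N" & vapply(nb, function(b) ordm(a, b) == 3, logical(1))]
        if (all(vapply(trip, function(t) length(heavy_nbrs[[t]]) == 1, logical(1))))
          set("nitrile")
      }

      if (length(dS) == 1 && length(dO) == 0 && length(dN) == 0) {
        sN <- sing[el[sing] == "N"]
        if (length(sN)) {
          set("thioamide")
          if (length(sN) >= 2) set("thiourea")
        }
      }

    }

    if (ea == "C") {
      # halides on any carbon, aryl vs alkyl by the carbon's aromaticity
      hal <- nb[el[nb] %in% .HALOGENS]
      for (x in hal) {
        kind <- c(F = "fluoride", Cl = "chloride", Br = "bromide",
                  I = "iodide", At = "iodide")[el[x]]
        set(paste0(if (at$aromatic[a]) "aryl_" else "alkyl_", kind))
      }
    }

    if (ea == "N" && !at$aromatic[a]) {
      dnb <- dbl_nbrs[[a]]
      has_double <- length(dnb) > 0 ||
        any(vapply(nb, function(b) ordm(a, b) >= 2, logical(1)))
      if (!has_double && at$charge[a] == 0) {
        others <- nb
        het <- others[is_heteroatom(el[others])]
        acylnb <- others[el[others] == "C" & (is_acyl[others] | is_sulfonyl[others])]
        if (!length(het) && !length(acylnb) && length(others) >= 1 &&
            all(el[others] == "C")) {
          set("amine")
          if (length(others) == 1) {
            set("primary_amine")
            if (at$aromatic[others[1]]) set("primary_aromatic_amine")
            else set("primary_aliphatic_amine")
          } else if (length(others) == 2) set("secondary_amine")
          else set("tertiary_amine")
        }
        nN <- others[el[others] == "N"]
        for (b in nN) {
          if (!sgl(a, b)) next
          b_dbl <- length(dbl_nbrs[[b]]) > 0
          b_acyl <- any(el[heavy_nbrs[[b]]] == "C" &
                        (is_acyl[heavy_nbrs[[b]]] | is_sulfonyl[heavy_nbrs[[b]]]))
          a_acyl <- any(el[nb] == "C" & (is_acyl[nb] | is_sulfonyl[nb]))
          if (!b_dbl && !b_acyl && !a_acyl && !at$aromatic[b])
            set("hydrazine")
        }
        nO <- others[el[others] == "O"]
        for (o in nO) {
          if (sgl(a, o) && at$total_h[o] >= 1 && length(heavy_nbrs[[o]]) == 1)
            set("hydroxylamine")
        }
      }
      # nitro / nitroso / azide / diazo
      termO <- nb[el[nb] == "O" & vapply(nb, function(b)
        length(heavy_nbrs[[b]]) == 1, logical(1))]
      if (length(termO) >= 2) {
        dblO <- sum(vapply(termO, function(o) dbl(a, o), logical(1)))
        chgO <- sum(at$charge[termO] < 0)
        if (dblO >= 2 || (dblO >= 1 && chgO >= 1)) set("nitro")
      } else if (length(termO) == 1 && dbl(a, termO[1]) &&
                 length(nb) == 2 && !hit["nitro"]) {
        set("nitroso")
      }
      nN <- nb[el[nb] == "N"]
      if (length(nN) == 2) {
        tot <- sum(vapply(nN, function(b) ordm(a, b), numeric(1)))
        if (tot >= 4) set("azide")
      }
      if (length(nb) == 1 && el[nb] == "N" && ordm(a, nb[1]) >= 2) {
        other <- setdiff(heavy_nbrs[[nb[1]]], a)
        if (any(el[other] == "C") && !any(el[other] == "N")) set("diazo")
      }
    }

    if (ea == "S") {
      sing <- nb[vapply(nb, function(b) sgl(a, b), logical(1))]
      sC <- sing[el[sing] == "C"]
      dO <- dbl_nbrs[[a]][el[dbl_nbrs[[a]]] == "O"]
      if (!length(dbl_nbrs[[a]]) && !at$aromatic[a] && at$charge[a] == 0) {
        if (at$total_h[a] >= 1 && length(nb) == 1 && length(sC) == 1)
          set("thiol")
        if (length(sC) == 2 && length(nb) == 2) set("thioether")
        sS <- sing[el[sing] == "S"]
        if (length(sS) && length(sC) >= 1) set("disulfide")
      }
      if (length(dO) == 1 && length(sC) == 2) set("sulfoxide")
      if (length(dO) >= 2) {
        sN <- sing[el[sing] == "N"]
        sO <- sing[el[sing] == "O"]
        if (length(sN)) set("sulfonamide")
        for (o in sO) {
          if (at$total_h[o] >= 1 && length(heavy_nbrs[[o]]) == 1)
            set("sulfonic_acid")
          else if (sum(el[heavy_nbrs[[o]]] == "C") >= 1) set("sulfonate_ester")
        }
        if (length(sC) == 2) set("sulfone")
      }
    }

    if (ea == "P") {
      dO <- dbl_nbrs[[a]][el[dbl_nbrs[[a]]] == "O"]
      sO <- nb[el[nb] == "O" & vapply(nb, function(b) sgl(a, b), logical(1))]
      if (length(dO) >= 1 && length(sO) >= 2) set("phosphate")
    }
  }

  positions <- .FG_TABLE$position[hit]
  descriptor <- bs_set(bitstring(256), positions)
  structure(list(
    descriptor = descriptor,
    segments = bs_segments(descriptor),
    positions = positions,
    names = .FG_TABLE$name[hit],
    ids = .FG_TABLE$id[hit]
  ), class = "fg_profile")
}

#' @export
print.fg_profile <- function(x, ...) {
  cat(sprintf("<functional groups: %d detected>\n", length(x$positions)))
  if (length(x$names)) cat(paste0("  ", x$names, collapse = "\n"), "\n")
  invisible(x)
}

#' Encode a functional-group query as 32-bit segments
#'
#' @param positions set of selected global bit positions (0-based, < 256)
#' @return a double vector of eight unsigned 32-bit segment values; segment
#'   `i %/% 32 + 1` carries bit `i %% 32` for each selected position `i`.
#' @examples
#' encode_group_query(c(3, 33, 38))  # 8, 66, 0, 0, 0, 0, 0, 0
#' @export
encode_group_query <- function(positions) {
  positions <- as.integer(positions)
  if (length(positions) && (any(positions < 0) || any(positions >= 256)))
    stop("encode_group_query: positions must lie in 0..255")
  bs_segments(bs_set(bitstring(256), positions))
}

#' Bitwise-AND mask predicates for a segment-encoded query
#'
#' One predicate per non-zero segment with the semantics
#' `stored_segment AND mask = mask`, i.e. the stored descriptor must contain
#' every selected bit.  An all-zero query yields no predicates and matches
#' everything.
#'
#' @param segments eight unsigned 32-bit segment values
#' @return a data frame with columns `segment` (1-based column index, as in
#'   fg01..fg08) and `mask`.
#' @export
mask_predicates <- function(segments) {
  nz <- which(segments != 0)
  data.frame(segment = nz, mask = segments[nz])
}

#' Test a stored descriptor against mask predicates
#' @param segments stored descriptor segments
#' @param predicates result of [mask_predicates()]
#' @return `TRUE` when every predicate is satisfied.
#' @export
satisfies_masks <- function(segments, predicates) {
  for (i in seq_len(nrow(predicates))) {
    s <- predicates$segment[i]
    m <- predicates$mask[i]
    if (.and32(segments[s], m) != m) return(FALSE)
  }
  TRUE
}

# bitwise AND of two unsigned 32-bit values carried as doubles
.and32 <- function(a, b) {
  r <- 0; bit <- 1
  for (k in 1:32) {
    if (a %% 2 == 1 && b %% 2 == 1) r <- r + bit
    a <- a %/% 2; b <- b %/% 2; bit <- bit * 2
    if (a == 0 || b == 0) break
  }
  r
}
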