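#' @title Built-in molecules, reactions and a seeded random-molecule generator
#' @description
#' Deterministic test inputs: a library of named small molecules (drug
#' molecules, aromaticity edge cases, stereochemistry probes) shipped as
#' V2000 connection tables, three toy reactions with consistent atom maps,
#' and a seeded generator of random valence-correct molecules for
#' property-style testing, with a companion needle extractor that produces
#' guaranteed substructures.
#' @name fixtures
NULL

#' Named built-in molecules
#'
#' Returns a named character vector of molfile texts.  Includes, among
#' others: `ethyl_acetate`, `caffeine`, `ellipticine`, `sulfanilamide`,
#' `diazepam`, `nag_glycoside` (N-acetyl-glucosamine methyl glycoside,
#' drawn without stereo descriptors), both benzene Kekule variants
#' (`benzene_kekule_a`/`b`, plus `benzene` as an alias of variant a),
#' `toluene`, `furan`, `pyridine`, `pyridone_2`, `pyridone_4`, `tropylium`,
#' `cyclopentadienide`, `cyclohexane`, `cyclooctatetraene`, `naphthalene`,
#' `quinoline`, `phenylhydrazine`, `e_2_butene`/`z_2_butene` (2D with
#' geometry), and `chfclbr_r_2d`/`chfclbr_s_2d`/`chfclbr_r_3d`/
#' `chfclbr_s_3d` (bromochlorofluoromethane enantiomers as wedge-annotated
#' 2D and true 3D files).  All entries parse and perceive cleanly.
#'
#' @return named character vector of molfile strings.
#' @export
builtin_molecules <- function() {
  mols <- .BUILTIN_MOLBLOCKS
  # second Kekule variant of benzene: shift every double bond by one
  ben <- strsplit(mols[["benzene"]], "\n", fixed = TRUE)[[1]]
  bond_rows <- 11:16
  orders <- as.integer(substr(ben[bond_rows], 7, 9))
  flipped <- ifelse(orders == 1L, 2L, 1L)
  ben[bond_rows] <- paste0(substr(ben[bond_rows], 1, 6),
                           sprintf("%3d", flipped),
                           substr(ben[bond_rows], 10, nchar(ben[bond_rows])))
  out <- c(mols,
           benzene_kekule_a = unname(mols[["benzene"]]),
           benzene_kekule_b = paste0(paste(ben, collapse = "\n"), "\n"))
  out
}

.with_maps <- function(text, maps) {
  mol <- parse_molfile(text)
  mol$atoms$map[seq_along(maps)] <- as.integer(maps)
  mol
}

#' Built-in toy reactions
#'
#' Three mapped reactions in MDL RXN format:
#' `imine_formation` (methylamine + acetaldehyde -> N-methyl ethanimine +
#' water), `hydrazide_formation` (methyl acetate + hydrazine ->
#' acetohydrazide + methanol) and `urea_formation` (methyl isocyanate +
#' methylamine -> 1,3-dimethylurea).  Atom map classes are consistent: each
#' class appears on one reactant atom and one product atom.
#'
#' @return named character vector of RXN strings.
#' @export
builtin_reactions <- function() {
  m <- builtin_molecules()
  rxn <- function(reactants, products) {
    r <- structure(list(reactants = reactants, products = products),
                   class = "reaction")
    write_rxnfile(r)
  }
  c(
    # CH3NH2(C1 N2) + CH3CHO(C3 C4 O5) -> CH3N=CHCH3(C4 C... ) + H2O
    imine_formation = rxn(
      list(.with_maps(m[["methylamine"]], c(1, 2)),
           .with_maps(m[["acetaldehyde"]], c(3, 4, 5))),
      list(.with_maps(m[["methanimine_n_methyl"]], c(3, 4, 2, 1)),
           .with_maps(m[["water"]], c(5)))),
    # CH3-O-C(=O)CH3 (C1 O2 C3 C4 O5) + H2N-NH2 (N6 N7)
    #   -> CH3C(=O)NHNH2 (C4 C3 O5 N6 N7) + CH3OH (C1 O2)
    hydrazide_formation = rxn(
      list(.with_maps(m[["methyl_acetate"]], c(1, 2, 3, 4, 5)),
           .with_maps(m[["hydrazine"]], c(6, 7))),
      list(.with_maps(m[["acetohydrazide"]], c(4, 3, 5, 6, 7)),
           .with_maps(m[["methanol"]], c(1, 2)))),
    # CH3-N=C=O (C1 N2 C3 O4) + CH3NH2 (C5 N6)
    #   -> CH3NH-C(=O)-NHCH3 (C1 N2 C3 O4 N6 C5)
    urea_formation = rxn(
      list(.with_maps(m[["methyl_isocyanate"]], c(1, 2, 3, 4)),
           .with_maps(m[["methylamine"]], c(5, 6))),
      list(.with_maps(m[["dimethylurea"]], c(1, 2, 3, 4, 6, 5))))
  )
}

#' Default fragment dictionary
#'
#' A dictionary of common carbocyclic and heterocyclic ring systems used for
#' dictionary fingerprints.  Entries carry no explicit hydrogens, which
#' keeps the dictionary bits usable as sound pre-selection filters.
#'
#' @return a named list of perceived `molecule` objects, in fixed order.
#' @export
default_dictionary <- function() {
  names <- c("benzene", "pyridine", "pyrimidine", "pyrazine", "furan",
             "pyrrole", "thiophene", "imidazole", "pyrazole", "oxazole",
             "thiazole", "naphthalene", "quinoline", "isoquinoline",
             "indole", "benzofuran", "purine", "anthracene",
             "cyclopropane", "cyclopentane", "cyclohexane", "piperidine",
             "tetrahydrofuran", "morpholine")
  m <- builtin_molecules()
  out <- lapply(names, function(nm) perceive(parse_molfile(m[[nm]])))
  stats::setNames(out, names)
}

# run `expr` under a private RNG stream so generation is reproducible and
# leaves the caller's RNG state untouched
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a random valence-correct molecule
#'
#' Grows a connected spanning tree atom by atom, closes rings between atoms
#' with free valence, then upgrades a fraction of bonds to double or triple
#' bonds where both ends can accommodate them, and optionally places a few
#' formal charges.  The default profile emulates drug-like organic
#' molecules: 10-40 heavy atoms, about 70% carbon, and a ring-closure rate
#' tuned to give two to three rings on average.  Identical seeds give
#' byte-identical molfiles, and every generated molecule passes perception
#' without valence warnings.
#'
#' @param seed integer seed; the sole source of randomness
#' @param n_atoms inclusive range for the heavy-atom count
#' @param p_element named sampling weights for elements other than the
#'   implicit carbon remainder
#' @param ring_closures mean number of attempted ring closures
#' @param p_double,p_triple per-bond upgrade probabilities
#' @param p_charge per-molecule probability of carrying one charged site
#' @return a `molecule` (unperceived), with its molfile text in
#'   `attr(, "molfile")`.
#' @export
generate_molecule <- function(seed, n_atoms = c(10, 40),
                              p_element = c(N = 0.12, O = 0.12, S = 0.03,
                                            F = 0.02, Cl = 0.03),
                              ring_closures = 2.5,
                              p_double = 0.15, p_triple = 0.01,
                              p_charge = 0.02) {
  .with_seed(seed, {
    n <- if (length(n_atoms) == 2) sample(n_atoms[1]:n_atoms[2], 1) else n_atoms
    probs <- c(p_element, C = 1 - sum(p_element))
    els <- sample(names(probs), n, replace = TRUE, prob = probs)
    # conservative generation valences (lowest standard state) keep the
    # output drug-like and guarantee clean perception
    genval <- c(C = 4, N = 3, O = 2, S = 2, F = 1, Cl = 1, Br = 1, I = 1)
    # halogens are terminal: grow the polyvalent skeleton first (which
    # always keeps spare valence), then append halogens up to capacity
    hal <- els %in% .HALOGENS
    els <- c(els[!hal], els[hal])
    n_skel <- sum(!hal)
    if (n_skel < 2) { els <- c("C", "C", els[-(1:2)]); n_skel <- 2 }
    spare <- sum(genval[els[seq_len(n_skel)]]) - 2 * (n_skel - 1)
    if (n - n_skel > spare) {
      els[(n_skel + spare + 1):n] <- "C"
      n_skel <- n - (n - n_skel - spare) # recount after conversion
      hal2 <- els %in% .HALOGENS
      els <- c(els[!hal2], els[hal2])
      n_skel <- sum(!hal2)
    }
    maxval <- genval[els]
    a1 <- integer(0); a2 <- integer(0); order <- integer(0)
    used <- numeric(n)   # consumed valence
    for (i in 2:n) {
      host <- which(used[seq_len(i - 1)] < maxval[seq_len(i - 1)] &
                    !(els[seq_len(i - 1)] %in% .HALOGENS))
      h <- if (length(host) == 1) host else sample(host, 1)
      a1 <- c(a1, h); a2 <- c(a2, i)
      used[h] <- used[h] + 1; used[i] <- used[i] + 1
    }
    # ring closures between non-adjacent atoms with spare valence
    n_close <- stats::rpois(1, ring_closures)
    if (n_close > 0) {
      adjkey <- paste(pmin(a1, a2), pmax(a1, a2))
      dist_from <- function(s) {
        d <- rep(NA_integer_, n); d[s] <- 0L; q <- s
        adj <- vector("list", n)
        for (k in seq_along(a1)) {
          adj[[a1[k]]] <- c(adj[[a1[k]]], a2[k])
          adj[[a2[k]]] <- c(adj[[a2[k]]], a1[k])
        }
        while (length(q)) {
          v <- q[1]; q <- q[-1]
          for (w in adj[[v]]) if (is.na(d[w])) { d[w] <- d[v] + 1L; q <- c(q, w) }
        }
        d
      }
      for (k in seq_len(n_close)) {
        open <- which(used < maxval & !(els %in% .HALOGENS))
        if (length(open) < 2) break
        u <- if (length(open) == 1) open else sample(open, 1)
        d <- dist_from(u)
        cand <- open[open != u & !is.na(d[open]) & d[open] >= 2 & d[open] <= 6]
        cand <- cand[!(paste(pmin(u, cand), pmax(u, cand)) %in% adjkey)]
        if (!length(cand)) next
        v <- if (length(cand) == 1) cand else sample(cand, 1)
        a1 <- c(a1, u); a2 <- c(a2, v)
        adjkey <- c(adjkey, paste(min(u, v), max(u, v)))
        used[u] <- used[u] + 1; used[v] <- used[v] + 1
      }
    }
    order <- rep(1L, length(a1))
    for (k in seq_along(order)) {
      i <- a1[k]; j <- a2[k]
      if (els[i] %in% .HALOGENS || els[j] %in% .HALOGENS) next
      r <- stats::runif(1)
      if (r < p_triple && used[i] + 2 <= maxval[i] && used[j] + 2 <= maxval[j] &&
          els[i] %in% c("C", "N") && els[j] %in% c("C", "N")) {
        order[k] <- 3L; used[i] <- used[i] + 2; used[j] <- used[j] + 2
      } else if (r < p_triple + p_double &&
                 used[i] + 1 <= maxval[i] && used[j] + 1 <= maxval[j]) {
        order[k] <- 2L; used[i] <- used[i] + 1; used[j] <- used[j] + 1
      }
    }
    charge <- integer(n)
    if (stats::runif(1) < p_charge) {
      site <- which(els == "N" & used < 4)
      if (length(site))
        charge[if (length(site) == 1) site else sample(site, 1)] <- 1L
    }
    atoms <- data.frame(
      element = els, charge = charge, isotope = 0L, radical = 0L,
      x = 0, y = 0, z = 0, map = 0L, aromatic = FALSE,
      stringsAsFactors = FALSE)
    bonds <- data.frame(a1 = a1, a2 = a2, order = order, stereo = 0L,
                        aromatic = FALSE, stringsAsFactors = FALSE)
    mol <- new_molecule(atoms, bonds, name = sprintf("generated-%d", seed))
    attr(mol, "molfile") <- write_molfile(mol)
    mol
  })
}

#' Extract a guaranteed-substructure needle
#'
#' Deletes `n_drop` randomly chosen terminal heavy atoms from a molecule,
#' skipping any deletion that would change the aromaticity flags of the
#' remaining atoms or bonds, so that the result is a substructure of the
#' input with a guaranteed `TRUE` match verdict.
#'
#' @param mol a `molecule` (perceived or not)
#' @param n_drop number of leaf deletions to attempt
#' @param seed integer seed
#' @param min_atoms do not shrink below this many atoms
#' @return a perceived `molecule` needle.
#' @export
extract_needle <- function(mol, n_drop, seed, min_atoms = 3) {
  ref <- perceive(mol)
  cur <- ref
  .with_seed(seed, {
    for (k in seq_len(n_drop)) {
      if (nrow(cur$atoms) <= min_atoms) break
      deg <- integer(nrow(cur$atoms))
      for (i in seq_len(nrow(cur$bonds))) {
        deg[cur$bonds$a1[i]] <- deg[cur$bonds$a1[i]] + 1L
        deg[cur$bonds$a2[i]] <- deg[cur$bonds$a2[i]] + 1L
      }
      leaves <- which(deg == 1 & !is_hydrogen(cur$atoms$element))
      if (length(leaves) > 1) leaves <- sample(leaves, length(leaves))
      for (lf in leaves) {
        cand <- .delete_atom(cur, lf)
        cand_p <- perceive(cand)
        keep <- setdiff(seq_len(nrow(cur$atoms)), lf)
        if (identical(cand_p$atoms$aromatic, cur$atoms$aromatic[keep]) &&
            .bond_flags_match(cur, cand_p, lf)) {
          cur <- cand_p
          break
        }
      }
    }
  })
  cur
}

.delete_atom <- function(mol, a) {
  keep <- setdiff(seq_len(nrow(mol$atoms)), a)
  remap <- integer(nrow(mol$atoms))
  remap[keep] <- seq_along(keep)
  atoms <- mol$atoms[keep, seq_len(9), drop = FALSE]  # raw columns only
  rownames(atoms) <- NULL
  atoms$aromatic <- FALSE
  bonds <- mol$bonds[mol$bonds$a1 != a & mol$bonds$a2 != a,
                     c("a1", "a2", "order", "stereo"), drop = FALSE]
  bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  bonds$aromatic <- FALSE
  rownames(bonds) <- NULL
  new_molecule(atoms, bonds, name = mol$name)
}

.bond_flags_match <- function(old, new, dropped) {
  old_b <- old$bonds[old$bonds$a1 != dropped & old$bonds$a2 != dropped, ]
  identical(unname(new$bonds$aromatic), unname(old_b$aromatic))
}
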