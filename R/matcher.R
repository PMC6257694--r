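#' @title Atom-by-atom structure matching
#' @description
#' Exact and substructure matching by recursive comparison: a reference atom
#' is selected in the query ("needle"), all of its possible counterparts in
#' the candidate ("haystack") are enumerated, and the substituent paths are
#' compared recursively under a per-atom-pair compatibility matrix.  Atom
#' pairs must agree on element, charge and aromaticity (plus hybridization
#' subtype in strict mode); bond pairs must agree on bond class (aromatic
#' matches aromatic, otherwise equal order).  Explicit hydrogens in the
#' needle act as minimum-hydrogen constraints on the matched heavy atom.
#' Optional checks compare E/Z double-bond geometry and R/S parity across
#' the mapping.
#' @name matcher
NULL

#' Morgan extended-connectivity ranks
#'
#' Iterative refinement: atoms start from an invariant built from heavy-atom
#' degree, element, charge and subtype; each round re-ranks atoms by their
#' current rank plus the sorted ranks of their neighbours, until the number
#' of distinct ranks stops increasing.
#'
#' @param mol a perceived `molecule`
#' @return an integer rank per atom; symmetry-equivalent atoms share ranks.
#' @export
morgan_ranks <- function(mol) {
  stopifnot(mol$perceived)
  n <- nrow(mol$atoms)
  if (n == 0) return(integer(0))
  adj <- adjacency_list(mol)
  key <- paste(mol$atoms$element, mol$atoms$charge, mol$atoms$subtype,
               vapply(adj, length, integer(1)))
  rank <- match(key, sort(unique(key)))
  n_classes <- length(unique(rank))
  repeat {
    key <- vapply(seq_len(n), function(a)
      paste(rank[a], paste(sort(rank[adj[[a]]]), collapse = ","), sep = "|"),
      character(1))
    new_rank <- match(key, sort(unique(key)))
    k <- length(unique(new_rank))
    if (k <= n_classes) break
    rank <- new_rank
    n_classes <- k
  }
  rank
}

#' Select a reference atom for matching
#'
#' The `heuristic` method maximizes (heavy-atom degree, heteroatom-neighbour
#' count, element rarity within the molecule) lexicographically; `morgan`
#' picks an atom of the rarest Morgan rank.  Ties break to the lowest atom
#' index; hydrogens are never selected unless nothing else exists.
#'
#' @param mol a perceived, non-empty `molecule`
#' @param method `"heuristic"` (default) or `"morgan"`
#' @return a 1-based atom index.
#' @export
select_reference_atom <- function(mol, method = c("heuristic", "morgan")) {
  method <- match.arg(method)
  stopifnot(mol$perceived)
  n <- nrow(mol$atoms)
  if (n == 0) stop("select_reference_atom: empty molecule")
  cand <- which(!is_hydrogen(mol$atoms$element))
  if (!length(cand)) cand <- seq_len(n)
  if (method == "heuristic") {
    adj <- adjacency_list(mol)
    het <- vapply(cand, function(a)
      sum(is_heteroatom(mol$atoms$element[adj[[a]]])), integer(1))
    rarity <- -as.integer(table(mol$atoms$element)[mol$atoms$element[cand]])
    ord <- order(-mol$atoms$heavy_degree[cand], -het, -rarity * -1, cand)
    # rarity: fewer atoms of that element is better, i.e. larger -count
    ord <- order(-mol$atoms$heavy_degree[cand], -het, -(-rarity), cand)
    return(cand[ord[1]])
  }
  ranks <- morgan_ranks(mol)[cand]
  freq <- table(ranks)
  rare <- as.integer(freq[as.character(ranks)])
  cand[order(rare, cand)][1]
}

# per-atom-pair compatibility ("local match matrix")
.compat_matrix <- function(needle, haystack, opts) {
  na <- needle$atoms; ha <- haystack$atoms
  nh <- which(!is_hydrogen(na$element))
  hh <- which(!is_hydrogen(ha$element))
  m <- matrix(FALSE, nrow(na), nrow(ha))
  for (i in nh) {
    ok <- ha$element[hh] == na$element[i] &
      ha$aromatic[hh] == na$aromatic[i]
    if (!(opts$charge_agnostic && na$charge[i] == 0))
      ok <- ok & ha$charge[hh] == na$charge[i]
    if (na$isotope[i] != 0 || opts$mode == "exact")
      ok <- ok & ha$isotope[hh] == na$isotope[i]
    if (opts$strict || opts$mode == "exact")
      ok <- ok & ha$subtype[hh] == na$subtype[i]
    if (opts$mode == "exact") {
      ok <- ok & ha$heavy_degree[hh] == na$heavy_degree[i] &
        ha$total_h[hh] == na$total_h[i]
    } else {
      ok <- ok & ha$heavy_degree[hh] >= na$heavy_degree[i] &
        ha$total_h[hh] >= na$explicit_h[i]
    }
    m[i, hh] <- ok
  }
  m
}

.bond_class <- function(mol, bi) {
  if (mol$bonds$aromatic[bi] || mol$bonds$order[bi] == 4) 0L
  else mol$bonds$order[bi]
}

.match_options <- function(mode = "substructure", strict = FALSE,
                           check_geometry = FALSE, check_chirality = FALSE,
                           mappings = "none", charge_agnostic = FALSE,
                           max_mappings = 10000) {
  mode <- match.arg(mode, c("substructure", "exact"))
  mappings <- match.arg(mappings, c("none", "first", "all"))
  list(mode = mode, strict = strict, check_geometry = check_geometry,
       check_chirality = check_chirality, mappings = mappings,
       charge_agnostic = charge_agnostic, max_mappings = max_mappings)
}

#' Match a query structure against a candidate
#'
#' @param needle the query `molecule` (perceived)
#' @param haystack the candidate `molecule` (perceived, possibly via a
#'   tweaked molfile)
#' @param mode `"substructure"` (default) or `"exact"`; exact mode requires
#'   a bijection on heavy atoms with equal bond multiset, charges, isotopes
#'   and per-atom hydrogen totals
#' @param strict also require matching hybridization subtypes
#' @param check_geometry compare E/Z double-bond geometry (from 2D
#'   coordinates) across the mapping
#' @param check_chirality compare R/S parity (from wedge-augmented 2D or
#'   true 3D coordinates) across the mapping
#' @param mappings `"none"` (verdict only), `"first"`, or `"all"`
#' @param charge_agnostic let an uncharged needle atom match any haystack
#'   charge (default off: charges must agree)
#' @param max_mappings cap on enumerated mappings in `"all"` mode
#' @return a `match_result`: `verdict` (logical) and `mappings` (a list of
#'   integer vectors, `mappings[[k]][i]` = haystack atom matched to needle
#'   heavy atom i; empty unless requested).
#' @examples
#' fx <- lapply(builtin_molecules()[c("benzene", "toluene")],
#'              function(t) perceive(parse_molfile(t)))
#' match_mol(fx$benzene, fx$toluene)$verdict  # TRUE
#' @export
match_mol <- function(needle, haystack, mode = "substructure",
                      strict = FALSE, check_geometry = FALSE,
                      check_chirality = FALSE, mappings = "none",
                      charge_agnostic = FALSE, max_mappings = 10000) {
  opts <- .match_options(mode, strict, check_geometry, check_chirality,
                         mappings, charge_agnostic, max_mappings)
  if (!inherits(needle, "molecule") || !inherits(haystack, "molecule"))
    stop("match_mol: inputs must be molecules")
  if (!needle$perceived || !haystack$perceived)
    stop("match_mol: inputs must be perceived")
  .run_match(needle, haystack, opts)
}

.run_match <- function(needle, haystack, opts) {
  n_heavy <- which(!is_hydrogen(needle$atoms$element))
  h_heavy <- which(!is_hydrogen(haystack$atoms$element))
  empty <- list(verdict = FALSE, mappings = list())
  class(empty) <- "match_result"
  if (!length(n_heavy)) {
    empty$verdict <- TRUE
    return(empty)
  }
  if (opts$mode == "exact") {
    if (length(n_heavy) != length(h_heavy)) return(empty)
    nb <- needle$bonds; hb <- haystack$bonds
    n_hv_b <- sum(!is_hydrogen(needle$atoms$element[nb$a1]) &
                  !is_hydrogen(needle$atoms$element[nb$a2]))
    h_hv_b <- sum(!is_hydrogen(haystack$atoms$element[hb$a1]) &
                  !is_hydrogen(haystack$atoms$element[hb$a2]))
    if (n_hv_b != h_hv_b) return(empty)
  } else if (length(n_heavy) > length(h_heavy)) {
    return(empty)
  }
  compat <- .compat_matrix(needle, haystack, opts)
  if (any(rowSums(compat[n_heavy, , drop = FALSE]) == 0)) return(empty)

  n_adj <- adjacency_list(needle)
  h_adj <- adjacency_list(haystack)
  n_lookup <- bond_lookup(needle)
  h_lookup <- bond_lookup(haystack)
  nn <- nrow(needle$atoms); hn <- nrow(haystack$atoms)

  # visit order: reference atom first, then connected extension over heavy
  # atoms; disconnected components each restart from their own anchor
  ref <- select_reference_atom(needle)
  order_idx <- integer(0)
  seen <- logical(nn)
  anchor_of <- integer(0)
  queue_component <- function(start) {
    stack <- start
    seen[start] <<- TRUE
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      order_idx <<- c(order_idx, v)
      nb <- n_adj[[v]]
      nb <- nb[!seen[nb] & !is_hydrogen(needle$atoms$element[nb])]
      seen[nb] <<- TRUE
      stack <- c(stack, nb)
    }
  }
  queue_component(ref)
  for (v in n_heavy) if (!seen[v]) queue_component(v)

  map <- integer(nn)          # 0 = unmapped
  used <- logical(hn)
  results <- list()
  found <- FALSE

  bond_ok <- function(ni, hj) {
    # every needle bond from order_idx position ni's atom to already-mapped
    # atoms must exist in the haystack with the same bond class
    v <- order_idx[ni]
    for (w in n_adj[[v]]) {
      if (is_hydrogen(needle$atoms$element[w]) || map[w] == 0) next
      nbi <- bond_index(n_lookup, nn, v, w)
      hbi <- bond_index(h_lookup, hn, map[v], map[w])
      if (is.na(hbi)) return(FALSE)
      if (.bond_class(needle, nbi) != .bond_class(haystack, hbi)) return(FALSE)
    }
    TRUE
  }

  stereo_ok <- function() {
    (!opts$check_geometry || .geometry_consistent(needle, haystack, map,
                                                  n_adj, h_adj, n_lookup,
                                                  h_lookup)) &&
    (!opts$check_chirality || .chirality_consistent(needle, haystack, map,
                                                    n_adj, h_adj, n_lookup,
                                                    h_lookup))
  }

  complete <- function() {
    if (opts$mode == "exact") {
      # bijection holds by counts; verify all haystack heavy bonds are hit
      hb <- haystack$bonds
      hv <- !is_hydrogen(haystack$atoms$element[hb$a1]) &
            !is_hydrogen(haystack$atoms$element[hb$a2])
      mapped_h <- logical(hn)
      mapped_h[map[map > 0]] <- TRUE
      if (!all(mapped_h[hb$a1[hv]] & mapped_h[hb$a2[hv]])) return(FALSE)
    }
    stereo_ok()
  }

  extend <- function(pos) {
    if (found && opts$mappings != "all") return()
    if (length(results) >= opts$max_mappings) return()
    if (pos > length(order_idx)) {
      if (complete()) {
        found <<- TRUE
        if (opts$mappings != "none")
          results[[length(results) + 1]] <<- map[n_heavy]
      }
      return()
    }
    v <- order_idx[pos]
    # candidate images: neighbours of an already-mapped neighbour, or any
    # unused compatible atom when the component anchor is being placed
    anchored <- FALSE
    cands <- NULL
    for (w in n_adj[[v]]) {
      if (!is_hydrogen(needle$atoms$element[w]) && map[w] > 0) {
        anchored <- TRUE
        cands <- h_adj[[map[w]]]
        break
      }
    }
    if (!anchored) cands <- seq_len(hn)
    for (h in cands) {
      if (used[h] || !compat[v, h]) next
      map[v] <<- h
      if (bond_ok(pos)) {
        used[h] <<- TRUE
        extend(pos + 1)
        used[h] <<- FALSE
      }
      map[v] <<- 0L
      if (found && opts$mappings != "all") return()
    }
  }
  extend(1)

  res <- list(verdict = found,
              mappings = if (opts$mappings == "none") list() else {
                ms <- lapply(results, function(m)
                  stats::setNames(m, n_heavy))
                if (opts$mappings == "first" && length(ms)) ms[1] else ms
              })
  class(res) <- "match_result"
  res
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match: %s%s>\n", if (x$verdict) "T" else "F",
              if (length(x$mappings)) sprintf(", %d mapping(s)", length(x$mappings)) else ""))
  invisible(x)
}

#' Enumerate atom/atom mappings of a match
#'
#' Convenience wrapper around [match_mol()] with mappings requested; `all`
#' engages the global match matrix mode and returns every distinct
#' embedding of the needle into the haystack.
#'
#' @inheritParams match_mol
#' @param which `"all"` (default) or `"first"`
#' @return a list of named integer vectors (needle atom -> haystack atom).
#' @export
enumerate_mappings <- function(needle, haystack, which = c("all", "first"),
                               mode = "substructure", strict = FALSE,
                               check_geometry = FALSE,
                               check_chirality = FALSE,
                               max_mappings = 10000) {
  which <- match.arg(which)
  match_mol(needle, haystack, mode = mode, strict = strict,
            check_geometry = check_geometry,
            check_chirality = check_chirality,
            mappings = which, max_mappings = max_mappings)$mappings
}

# ---- stereochemistry ------------------------------------------------------

.has_2d <- function(mol) {
  any(mol$atoms$x != 0 | mol$atoms$y != 0) && all(mol$atoms$z == 0)
}

.has_3d <- function(mol) any(mol$atoms$z != 0)

# side of point p relative to the directed axis a -> b (sign of the z
# component of the 2D cross product)
.side <- function(ax, ay, bx, by, px, py) {
  sign((bx - ax) * (py - ay) - (by - ay) * (px - ax))
}

# E/Z: for every needle double bond with defined 2D geometry, the relative
# side of the chosen substituents must be reproduced by their images
.geometry_consistent <- function(needle, haystack, map, n_adj, h_adj,
                                 n_lookup, h_lookup) {
  if (!.has_2d(needle) || !.has_2d(haystack)) return(TRUE)
  ring_bond <- bond_ring_counts(needle) > 0
  for (bi in seq_len(nrow(needle$bonds))) {
    if (needle$bonds$order[bi] != 2 || needle$bonds$aromatic[bi] ||
        ring_bond[bi]) next
    a <- needle$bonds$a1[bi]; b <- needle$bonds$a2[bi]
    if (map[a] == 0 || map[b] == 0) next
    na_subs <- setdiff(n_adj[[a]], b)
    nb_subs <- setdiff(n_adj[[b]], a)
    na_subs <- na_subs[!is_hydrogen(needle$atoms$element[na_subs]) & map[na_subs] > 0]
    nb_subs <- nb_subs[!is_hydrogen(needle$atoms$element[nb_subs]) & map[nb_subs] > 0]
    if (!length(na_subs) || !length(nb_subs)) next
    sa <- min(na_subs); sb <- min(nb_subs)
    at <- needle$atoms
    s_n <- .side(at$x[a], at$y[a], at$x[b], at$y[b], at$x[sa], at$y[sa]) *
           .side(at$x[a], at$y[a], at$x[b], at$y[b], at$x[sb], at$y[sb])
    ht <- haystack$atoms
    ha <- map[a]; hb <- map[b]; hsa <- map[sa]; hsb <- map[sb]
    s_h <- .side(ht$x[ha], ht$y[ha], ht$x[hb], ht$y[hb], ht$x[hsa], ht$y[hsa]) *
           .side(ht$x[ha], ht$y[ha], ht$x[hb], ht$y[hb], ht$x[hsb], ht$y[hsb])
    if (s_n == 0 || s_h == 0) next
    if (s_n != s_h) return(FALSE)
  }
  TRUE
}

# signed-volume parity at a candidate stereocenter; wedge bonds lift 2D
# coordinates out of plane (up = +1 toward the viewer)
.atom_parity <- function(mol, center, nbrs, adj, lookup) {
  n <- nrow(mol$atoms)
  at <- mol$atoms
  use3d <- .has_3d(mol)
  z_of <- function(a) {
    if (use3d) return(at$z[a])
    0
  }
  zc <- z_of(center)
  if (!use3d) {
    # apply wedges drawn from the center
    wz <- stats::setNames(numeric(length(nbrs)), nbrs)
    for (b in nbrs) {
      bi <- bond_index(lookup, n, center, b)
      if (mol$bonds$a1[bi] == center) {
        if (mol$bonds$stereo[bi] == 1) wz[as.character(b)] <- 1
        if (mol$bonds$stereo[bi] == 6) wz[as.character(b)] <- -1
      }
    }
    # a wedge from the center to an unmapped (e.g. hydrogen) neighbour is
    # handled by the caller via center displacement
    zs <- wz[as.character(nbrs)]
  } else {
    zs <- vapply(nbrs, z_of, numeric(1))
  }
  v <- cbind(at$x[nbrs] - at$x[center],
             at$y[nbrs] - at$y[center],
             zs - zc)
  if (nrow(v) < 3) return(0)
  d <- det(v[1:3, , drop = FALSE])
  if (abs(d) < 1e-9) return(0)
  sign(d)
}

.wedge_to_h <- function(mol, center, mapped_nbrs, adj, lookup) {
  # sign contribution of a wedge pointing from center to a neighbour that is
  # not part of the mapping (typically an explicit hydrogen): displacing
  # that neighbour up is equivalent to displacing the center down
  n <- nrow(mol$atoms)
  others <- setdiff(adj[[center]], mapped_nbrs)
  for (b in others) {
    bi <- bond_index(lookup, n, center, b)
    if (mol$bonds$a1[bi] == center) {
      if (mol$bonds$stereo[bi] == 1) return(-1)
      if (mol$bonds$stereo[bi] == 6) return(1)
    }
  }
  0
}

.chirality_consistent <- function(needle, haystack, map, n_adj, h_adj,
                                  n_lookup, h_lookup) {
  at <- needle$atoms
  for (a in seq_len(nrow(at))) {
    if (is_hydrogen(at$element[a]) || map[a] == 0) next
    nbrs <- n_adj[[a]]
    nbrs <- nbrs[!is_hydrogen(at$element[nbrs]) & map[nbrs] > 0]
    if (length(nbrs) < 3) next
    nbrs <- sort(nbrs)[1:3]
    # require distinguishable substituents so that symmetric centers are
    # never flagged as stereo mismatches
    keyn <- paste(at$element[nbrs], at$charge[nbrs])
    if (anyDuplicated(keyn)) next
    p_n <- .atom_parity(needle, a, nbrs, n_adj, n_lookup)
    if (p_n == 0) {
      adjp <- .wedge_to_h(needle, a, nbrs, n_adj, n_lookup)
      if (adjp == 0) next
      # displace the center out of plane and recompute
      p_n <- .parity_with_center_z(needle, a, nbrs, -adjp)
    }
    h <- map[a]; hn <- map[nbrs]
    p_h <- .atom_parity(haystack, h, hn, h_adj, h_lookup)
    if (p_h == 0) {
      adjp <- .wedge_to_h(haystack, h, hn, h_adj, h_lookup)
      if (adjp == 0) next
      p_h <- .parity_with_center_z(haystack, h, hn, -adjp)
    }
    if (p_n == 0 || p_h == 0) next
    if (p_n != p_h) return(FALSE)
  }
  TRUE
}

.parity_with_center_z <- function(mol, center, nbrs, zc) {
  at <- mol$atoms
  v <- cbind(at$x[nbrs] - at$x[center],
             at$y[nbrs] - at$y[center],
             rep(-zc, length(nbrs)))
  d <- det(v[1:3, , drop = FALSE])
  if (abs(d) < 1e-9) return(0)
  sign(d)
}
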