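#' @title Molecular perception: rings, aromaticity, atom subtypes
#' @description
#' Perception turns a parsed connection table into a fully annotated
#' molecular graph.  The ring set defaults to the set of all rings (SAR,
#' every simple cycle up to a size bound); for highly condensed systems
#' whose SAR exceeds a budget, a smallest-set-of-smallest-rings (SSSR)
#' cycle basis is used instead.  Each ring is then tested against the
#' Hueckel 4n+2 rule with a per-atom pi-electron contribution table, and
#' every atom receives a hybridization subtype.
#' @name perception
NULL

# standard valence lists used for implicit hydrogen counting; the smallest
# listed valence that accommodates the bond-order sum is chosen
.VALENCES <- list(
  H = 1, B = 3, C = 4, N = c(3, 5), O = 2, F = 1,
  Si = 4, P = c(3, 5), S = c(2, 4, 6), Cl = 1,
  As = c(3, 5), Se = c(2, 4, 6), Br = 1, I = 1, At = 1
)

.HALOGENS <- c("F", "Cl", "Br", "I", "At")

is_heteroatom <- function(el) !(el %in% c("C", "H", "D", "T"))
is_hydrogen <- function(el) el %in% c("H", "D", "T")

adjacency_list <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (i in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

bond_lookup <- function(mol) {
  n <- nrow(mol$atoms)
  key <- pmin(mol$bonds$a1, mol$bonds$a2) * (n + 1) +
    pmax(mol$bonds$a1, mol$bonds$a2)
  idx <- seq_len(nrow(mol$bonds))
  names(idx) <- key
  idx
}

bond_index <- function(lookup, n, a, b) {
  i <- lookup[as.character(pmin(a, b) * (n + 1) + pmax(a, b))]
  unname(i)
}

#' Enumerate the ring set of a molecule
#'
#' Lists all simple cycles with at most `max_ring_size` atoms (SAR).  Cycle
#' enumeration is canonical: each cycle is reported once, anchored at its
#' lowest-index atom.  If more than `ring_budget` cycles exist the SAR is
#' abandoned and an SSSR cycle basis (Horton candidate cycles, greedy GF(2)
#' independence selection, smallest first) is returned instead; its size is
#' the cyclomatic number of the graph.
#'
#' @param mol a `molecule`
#' @param max_ring_size largest ring reported (default 26)
#' @param ring_budget maximum SAR size before falling back to SSSR
#' @return a list with `rings` (list of atom-index vectors) and `method`
#'   ("SAR" or "fallback"); acyclic molecules give an empty ring list.
#' @export
perceive_rings <- function(mol, max_ring_size = 26, ring_budget = 1024) {
  adj <- adjacency_list(mol)
  n <- nrow(mol$atoms)
  # restrict to the 2-core: vertices outside it cannot lie on a cycle
  deg <- vapply(adj, length, integer(1))
  alive <- deg > 0
  repeat {
    drop <- which(alive & deg <= 1)
    if (!length(drop)) break
    alive[drop] <- FALSE
    for (v in drop) for (w in adj[[v]])
      if (alive[w]) deg[w] <- deg[w] - 1
  }
  rings <- list()
  overflow <- FALSE
  for (s in which(alive)) {
    if (overflow) break
    # DFS over vertices > s so each cycle is found at its minimum vertex;
    # direction fixed by requiring path[2] < final vertex
    path <- integer(max_ring_size)
    path[1] <- s
    onpath <- logical(n)
    onpath[s] <- TRUE
    dfs <- function(v, depth) {
      if (overflow) return()
      for (w in adj[[v]]) {
        if (!alive[w]) next
        if (w == s && depth >= 3 && path[2] < v) {
          rings[[length(rings) + 1]] <<- path[seq_len(depth)]
          if (length(rings) > ring_budget) overflow <<- TRUE
          if (overflow) return()
        } else if (w > s && !onpath[w] && depth < max_ring_size) {
          path[depth + 1] <<- w
          onpath[w] <<- TRUE
          dfs(w, depth + 1)
          onpath[w] <<- FALSE
        }
      }
    }
    dfs(s, 1)
  }
  if (!overflow) return(list(rings = rings, method = "SAR"))
  list(rings = .sssr(mol, adj, alive), method = "fallback")
}

# SSSR by Horton's candidate set + greedy GF(2)-independent selection
.sssr <- function(mol, adj, alive) {
  n <- nrow(mol$atoms)
  m <- nrow(mol$bonds)
  comp <- integer(n)
  cid <- 0
  for (s in seq_len(n)) {
    if (comp[s] || !alive[s]) next
    cid <- cid + 1
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (alive[w] && !comp[w]) {
        comp[w] <- cid; queue <- c(queue, w)
      }
    }
  }
  core_bonds <- which(alive[mol$bonds$a1] & alive[mol$bonds$a2])
  target <- length(core_bonds) - sum(alive) + cid
  if (target <= 0) return(list())
  # BFS shortest-path trees from every core vertex
  parent <- dist <- vector("list", n)
  for (s in which(alive)) {
    d <- rep(NA_integer_, n); p <- integer(n)
    d[s] <- 0L; queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (alive[w] && is.na(d[w])) {
        d[w] <- d[v] + 1L; p[w] <- v; queue <- c(queue, w)
      }
    }
    dist[[s]] <- d; parent[[s]] <- p
  }
  path_to <- function(s, v) {
    out <- v
    while (v != s) { v <- parent[[s]][v]; out <- c(out, v) }
    out
  }
  cands <- list()
  for (s in which(alive)) {
    for (bi in core_bonds) {
      x <- mol$bonds$a1[bi]; y <- mol$bonds$a2[bi]
      dx <- dist[[s]][x]; dy <- dist[[s]][y]
      if (is.na(dx) || is.na(dy)) next
      px <- path_to(s, x); py <- path_to(s, y)
      if (length(intersect(px, py)) != 1) next
      cyc <- c(rev(px), py[-length(py)])
      if (length(cyc) >= 3) cands[[length(cands) + 1]] <- cyc
    }
  }
  if (!length(cands)) return(list())
  # dedupe and sort by size
  keys <- vapply(cands, function(c) paste(sort(c), collapse = ","), character(1))
  cands <- cands[!duplicated(keys)]
  cands <- cands[order(vapply(cands, length, integer(1)))]
  lookup <- bond_lookup(mol)
  edge_vec <- function(cyc) {
    v <- logical(m)
    k <- length(cyc)
    for (i in seq_len(k)) {
      bi <- bond_index(lookup, n, cyc[i], cyc[if (i == k) 1 else i + 1])
      if (is.na(bi)) return(NULL)
      v[bi] <- TRUE
    }
    v
  }
  basis <- list(); chosen <- list()
  for (cyc in cands) {
    if (length(chosen) >= target) break
    v <- edge_vec(cyc)
    if (is.null(v)) next
    w <- v
    for (b in basis) {
      piv <- which(b)[1]
      if (w[piv]) w <- xor(w, b)
    }
    if (any(w)) {
      basis[[length(basis) + 1]] <- w
      chosen[[length(chosen) + 1]] <- cyc
    }
  }
  chosen
}

# pi-electron contribution of each atom of `ring`; NA means the atom cannot
# contribute a p orbital, which breaks conjugation
.pi_contribution <- function(mol, ring, adj, lookup) {
  n <- nrow(mol$atoms)
  in_any_ring <- attr(mol, "ring_atoms")
  vapply(ring, function(a) {
    el <- mol$atoms$element[a]
    chg <- mol$atoms$charge[a]
    nbrs <- adj[[a]]
    border <- function(b) mol$bonds$order[bond_index(lookup, n, a, b)]
    in_ring <- nbrs[nbrs %in% ring]
    out_ring <- setdiff(nbrs, in_ring)
    in_orders <- vapply(in_ring, border, numeric(1))
    out_orders <- if (length(out_ring)) vapply(out_ring, border, numeric(1)) else numeric(0)
    has_in_double <- any(in_orders == 2)
    has_in_arom <- any(in_orders == 4)
    if (any(in_orders == 3) || any(out_orders == 3)) return(NA_real_)
    if (has_in_double) return(1)
    if (has_in_arom) {
      # aromatic input bonds: pyrrole-type heteroatom (three sigma bonds or
      # an implicit hydrogen) donates the lone pair, otherwise pyridine-type
      if (el == "C") return(if (chg > 0) 0 else if (chg < 0) 2 else 1)
      sigma <- length(nbrs) + .implicit_h_one(mol, a, adj, lookup)
      return(if (sigma >= 3) 2 else 1)
    }
    exo_double <- out_ring[which(out_orders == 2)]
    if (length(exo_double)) {
      # exocyclic double bond: into another ring keeps normal conjugation
      # (Kekule forms of fused aromatics); onto a terminal atom (C=O of the
      # pyridones, C=C of fulvenes) contributes no electrons but keeps the
      # p orbital
      if (any(in_any_ring[exo_double])) return(1)
      return(0)
    }
    # no double bond at all
    if (el == "C") {
      if (chg < 0) return(2)
      if (chg > 0) return(0)
      return(NA_real_)                       # saturated carbon: break
    }
    if (el %in% c("N", "O", "S", "P", "Se", "As")) return(2)
    NA_real_
  }, numeric(1))
}

#' Flag aromatic rings, atoms and bonds
#'
#' Each perceived ring is classified with the Hueckel rule: the ring is
#' aromatic when every member can contribute a p orbital and the pi-electron
#' sum is 2, 6, 10, ... (4n+2).  Contributions: ring atom with an
#' endocyclic double bond, 1; heteroatom donating a free electron pair
#' (furan-type), 2; carbanion, 2; carbocation, 0; ring atom bearing an
#' exocyclic double bond to a terminal atom (2-/4-pyridone carbonyls), 0
#' without breaking conjugation.  An atom or bond is aromatic when it lies
#' on at least one aromatic ring.
#'
#' @param mol a `molecule` with rings perceived (see [perceive_rings()])
#' @return the molecule with `atoms$aromatic` and `bonds$aromatic` set.
#' @export
perceive_aromaticity <- function(mol) {
  adj <- adjacency_list(mol)
  lookup <- bond_lookup(mol)
  n <- nrow(mol$atoms)
  ring_atoms <- logical(n)
  for (r in mol$rings) ring_atoms[r] <- TRUE
  attr(mol, "ring_atoms") <- ring_atoms
  mol$atoms$aromatic <- logical(n)
  mol$bonds$aromatic <- logical(nrow(mol$bonds))
  for (ring in mol$rings) {
    contrib <- .pi_contribution(mol, ring, adj, lookup)
    if (any(is.na(contrib))) next
    total <- sum(contrib)
    if (total < 2 || total %% 4 != 2) next
    mol$atoms$aromatic[ring] <- TRUE
    k <- length(ring)
    for (i in seq_len(k)) {
      bi <- bond_index(lookup, n, ring[i], ring[if (i == k) 1 else i + 1])
      mol$bonds$aromatic[bi] <- TRUE
    }
  }
  attr(mol, "ring_atoms") <- NULL
  mol
}

.implicit_h_one <- function(mol, a, adj, lookup) {
  el <- mol$atoms$element[a]
  vals <- .VALENCES[[el]]
  if (is.null(vals)) return(0L)
  n <- nrow(mol$atoms)
  orders <- vapply(adj[[a]], function(b) {
    o <- mol$bonds$order[bond_index(lookup, n, a, b)]
    if (o == 4) 1.5 else o
  }, numeric(1))
  bsum <- ceiling(sum(orders))
  chg <- mol$atoms$charge[a]
  shift <- if (el == "C") -abs(chg) else chg
  shift <- shift - mol$atoms$radical[a] %/% 2   # doublet radical uses one valence
  for (v in vals) {
    if (v + shift >= bsum) return(as.integer(v + shift - bsum))
  }
  0L
}

#' Assign hybridization subtypes
#'
#' `sp` for atoms with a triple bond or two double bonds, `sp2` for atoms
#' with a double or aromatic bond, `sp3` otherwise; atoms on an aromatic
#' ring get the aromatic variant `ar`.  Also fills in heavy-atom degree and
#' the attached-hydrogen count (explicit H neighbours plus implicit
#' hydrogens from the standard valence tables, charge-adjusted, floored at
#' zero).  An atom whose bond-order sum exceeds every standard valence of
#' its element gets a perception warning.
#'
#' @param mol a `molecule` with aromaticity perceived
#' @return the molecule with `subtype`, `heavy_degree`, `explicit_h`,
#'   `implicit_h` and `total_h` atom columns.
#' @export
assign_atom_subtypes <- function(mol) {
  adj <- adjacency_list(mol)
  lookup <- bond_lookup(mol)
  n <- nrow(mol$atoms)
  subtype <- character(n)
  heavy_degree <- integer(n)
  explicit_h <- integer(n)
  implicit_h <- integer(n)
  warns <- character(0)
  for (a in seq_len(n)) {
    nbrs <- adj[[a]]
    els <- mol$atoms$element[nbrs]
    heavy_degree[a] <- sum(!is_hydrogen(els))
    explicit_h[a] <- sum(is_hydrogen(els))
    orders <- if (length(nbrs)) vapply(nbrs, function(b)
      mol$bonds$order[bond_index(lookup, n, a, b)], numeric(1)) else numeric(0)
    aromatic_bond <- length(nbrs) && any(
      mol$bonds$aromatic[vapply(nbrs, function(b)
        bond_index(lookup, n, a, b), numeric(1))] | orders == 4)
    subtype[a] <-
      if (sum(orders == 3) >= 1 || sum(orders == 2) >= 2) "sp"
      else if (mol$atoms$aromatic[a]) "ar"
      else if (any(orders == 2) || aromatic_bond) "sp2"
      else "sp3"
    implicit_h[a] <- .implicit_h_one(mol, a, adj, lookup)
    vals <- .VALENCES[[mol$atoms$element[a]]]
    if (!is.null(vals)) {
      bsum <- ceiling(sum(ifelse(orders == 4, 1.5, orders)))
      chg <- mol$atoms$charge[a]
      shift <- if (mol$atoms$element[a] == "C") -abs(chg) else chg
      if (bsum > max(vals) + max(shift, 0))
        warns <- c(warns, sprintf("atom %d (%s): valence %d exceeds element maximum",
                                  a, mol$atoms$element[a], bsum))
    }
  }
  mol$atoms$subtype <- subtype
  mol$atoms$heavy_degree <- heavy_degree
  mol$atoms$explicit_h <- explicit_h
  mol$atoms$implicit_h <- implicit_h
  mol$atoms$total_h <- explicit_h + implicit_h
  mol$warnings <- c(mol$warnings, warns)
  mol
}

#' Full perception pass
#'
#' Runs ring perception, aromaticity detection and subtype assignment and
#' marks the molecule perceived.  A molecule loaded from a tweaked molfile
#' skips ring search and aromaticity detection entirely (the stored flags
#' are trusted) unless `force = TRUE`; ring-dependent descriptors still
#' trigger a ring search on demand, but matching does not need one.
#' Perception is idempotent.
#'
#' @param mol a `molecule`
#' @param max_ring_size,ring_budget see [perceive_rings()]
#' @param force re-run ring search and aromaticity detection even for
#'   molecules loaded from tweaked files
#' @return the perceived molecule
#' @export
perceive <- function(mol, max_ring_size = 26, ring_budget = 1024,
                     force = FALSE) {
  stopifnot(inherits(mol, "molecule"))
  if (mol$perceived && !force) return(mol)
  if (mol$tweak && !force) {
    # aromaticity arrives precomputed; rings are still needed for ring
    # statistics, but the (expensive) aromaticity classification is skipped
    rs <- perceive_rings(mol, max_ring_size, ring_budget)
    mol$rings <- rs$rings
    mol$ring_method <- rs$method
  } else {
    rs <- perceive_rings(mol, max_ring_size, ring_budget)
    mol$rings <- rs$rings
    mol$ring_method <- rs$method
    mol <- perceive_aromaticity(mol)
  }
  mol <- assign_atom_subtypes(mol)
  mol$perceived <- TRUE
  mol
}

#' Ring membership count per bond
#' @param mol a perceived `molecule`
#' @return integer vector, one entry per bond
#' @export
bond_ring_counts <- function(mol) {
  lookup <- bond_lookup(mol)
  n <- nrow(mol$atoms)
  counts <- integer(nrow(mol$bonds))
  for (ring in mol$rings) {
    k <- length(ring)
    for (i in seq_len(k)) {
      bi <- bond_index(lookup, n, ring[i], ring[if (i == k) 1 else i + 1])
      counts[bi] <- counts[bi] + 1L
    }
  }
  counts
}
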