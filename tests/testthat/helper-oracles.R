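# Shared fixtures and independent oracles for the test suite.

# cache of perceived built-in molecules
.fixture_env <- new.env()
fx <- function(name) {
  if (is.null(.fixture_env[[name]]))
    .fixture_env[[name]] <- perceive(parse_molfile(builtin_molecules()[[name]]))
  .fixture_env[[name]]
}

h_el <- function(el) el %in% c("H", "D", "T")

# Independent brute-force subgraph-isomorphism oracle: needle heavy atoms
# are assigned in index order to any unused compatible haystack atom, with
# adjacency of every assigned pair re-checked at each step.  Deliberately
# shares no code with the package matcher (no reference atom, no
# compatibility matrix, no connected visit order).
oracle_subiso <- function(needle, haystack, exact = FALSE) {
  nh <- which(!h_el(needle$atoms$element))
  hh <- which(!h_el(haystack$atoms$element))
  if (!length(nh)) return(TRUE)
  if (exact && length(nh) != length(hh)) return(FALSE)
  if (length(nh) > length(hh)) return(FALSE)
  cls_mat <- function(m) {
    n <- nrow(m$atoms)
    M <- matrix(0L, n, n)
    for (i in seq_len(nrow(m$bonds))) {
      cls <- if (m$bonds$aromatic[i] || m$bonds$order[i] == 4) 9L
             else m$bonds$order[i]
      M[m$bonds$a1[i], m$bonds$a2[i]] <- cls
      M[m$bonds$a2[i], m$bonds$a1[i]] <- cls
    }
    M
  }
  NM <- cls_mat(needle); HM <- cls_mat(haystack)
  na <- needle$atoms; ha <- haystack$atoms
  assn <- integer(length(nh)); used <- logical(nrow(ha))
  n_heavy_bonds <- function(m) {
    sum(!h_el(m$atoms$element[m$bonds$a1]) & !h_el(m$atoms$element[m$bonds$a2]))
  }
  if (exact && n_heavy_bonds(needle) != n_heavy_bonds(haystack)) return(FALSE)
  rec <- function(k) {
    if (k > length(nh)) return(TRUE)
    i <- nh[k]
    for (j in hh) {
      if (used[j]) next
      if (ha$element[j] != na$element[i]) next
      if (ha$aromatic[j] != na$aromatic[i]) next
      if (ha$charge[j] != na$charge[i]) next
      if (na$isotope[i] != 0 && ha$isotope[j] != na$isotope[i]) next
      if (exact) {
        if (ha$total_h[j] != na$total_h[i]) next
        if (ha$isotope[j] != na$isotope[i]) next
      } else if (ha$total_h[j] < na$explicit_h[i]) next
      ok <- TRUE
      for (k2 in seq_len(k - 1)) {
        i2 <- nh[k2]
        nm <- NM[i, i2]; hm <- HM[j, assn[k2]]
        if (if (exact) nm != hm else (nm != 0L && hm != nm)) { ok <- FALSE; break }
      }
      if (!ok) next
      assn[k] <<- j; used[j] <<- TRUE
      if (rec(k + 1)) return(TRUE)
      used[j] <<- FALSE
    }
    FALSE
  }
  rec(1)
}

# attach n_extra random single-bonded decorations (C/N/O) to atoms that
# still have implicit hydrogens; used to build analog series around a core
decorate_molecule <- function(mol, n_extra, seed) {
  p <- perceive(mol)
  set.seed(seed)
  for (k in seq_len(n_extra)) {
    open <- which(p$atoms$implicit_h > 0 & !h_el(p$atoms$element))
    if (!length(open)) break
    host <- if (length(open) == 1) open else sample(open, 1)
    el <- sample(c("C", "C", "C", "N", "O"), 1)
    p$atoms <- rbind(p$atoms[, 1:9],
                     data.frame(element = el, charge = 0L, isotope = 0L,
                                radical = 0L, x = 0, y = 0, z = 0,
                                map = 0L, aromatic = FALSE,
                                stringsAsFactors = FALSE))
    p$bonds <- rbind(p$bonds[, c("a1", "a2", "order", "stereo")],
                     data.frame(a1 = host, a2 = nrow(p$atoms),
                                order = 1L, stereo = 0L))
    p$bonds$aromatic <- FALSE
    p$perceived <- FALSE; p$tweak <- FALSE
    p <- perceive(p)
  }
  p
}
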