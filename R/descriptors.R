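#' @title Pre-selection descriptors: molstat, hashed and dictionary fingerprints
#' @description
#' Three descriptor families support database pre-selection before any
#' atom-by-atom comparison: discrete structural counters ("molstat"), a
#' 512-bit hashed fingerprint of all linear path fragments of 3-8 atoms,
#' and a dictionary fingerprint with one bit per dictionary fragment found
#' as a substructure (plus an identity flag in the least significant bit).
#' @name descriptors
NULL

#' Names of the molstat counters, in storage order
#' @export
molstat_names <- function() c(
  "n_atoms", "n_bonds", "n_rings", "n_C", "n_C_sp", "n_C_sp2",
  "n_C_1het", "n_C_2het", "n_C_3plus_het",
  "n_CO_single", "n_CO_double", "n_CN_anyorder",
  paste0("n_ring_size_", 3:12), "n_ring_size_13plus",
  "n_rings_with_N", "n_rings_with_O", "n_rings_with_S",
  "n_heteroatoms", "n_halogens", "n_charged_atoms"
)

#' Compute the molecular-statistics counter vector
#'
#' Counts refer to heavy (non-hydrogen) atoms and the bonds between them.
#' The carbon-to-heteroatom counters are cumulative thresholds (a carbon
#' bonded to two heteroatoms counts under both `n_C_1het` and `n_C_2het`),
#' and perceived aromatic C-O bonds count under both `n_CO_single` and
#' `n_CO_double`; both conventions keep every counter monotone under the
#' substructure relation, which is what makes the counters safe as
#' pre-selection filters.
#'
#' @param mol a perceived `molecule`
#' @return a named integer vector (see [molstat_names()]) with attribute
#'   `ring_method` recording how the ring set was obtained.
#' @export
compute_molstat <- function(mol) {
  stopifnot(mol$perceived)
  at <- mol$atoms; bd <- mol$bonds
  heavy <- !is_hydrogen(at$element)
  hv_bond <- heavy[bd$a1] & heavy[bd$a2]
  ms <- stats::setNames(integer(length(molstat_names())), molstat_names())
  ms["n_atoms"] <- sum(heavy)
  ms["n_bonds"] <- sum(hv_bond)
  ms["n_rings"] <- length(mol$rings)
  isC <- at$element == "C"
  ms["n_C"] <- sum(isC)
  ms["n_C_sp"] <- sum(isC & at$subtype == "sp")
  # "sp2" here means: carries at least one double or aromatic bond.  (An sp
  # carbon with a double bond counts as well; like the cumulative
  # heteroatom counters below, this keeps the counter monotone under the
  # substructure relation.)
  has_pi <- logical(nrow(at))
  pi_bond <- bd$order == 2 | bd$order == 4 | bd$aromatic
  has_pi[bd$a1[pi_bond]] <- TRUE
  has_pi[bd$a2[pi_bond]] <- TRUE
  ms["n_C_sp2"] <- sum(isC & has_pi)
  adj <- adjacency_list(mol)
  het_nbrs <- vapply(seq_len(nrow(at)), function(a)
    sum(is_heteroatom(at$element[adj[[a]]])), integer(1))
  ms["n_C_1het"] <- sum(isC & het_nbrs >= 1)
  ms["n_C_2het"] <- sum(isC & het_nbrs >= 2)
  ms["n_C_3plus_het"] <- sum(isC & het_nbrs >= 3)
  el1 <- at$element[bd$a1]; el2 <- at$element[bd$a2]
  co <- (el1 == "C" & el2 == "O") | (el1 == "O" & el2 == "C")
  ms["n_CO_single"] <- sum(co & (bd$order == 1 | bd$aromatic | bd$order == 4))
  ms["n_CO_double"] <- sum(co & ((bd$order == 2 & !bd$aromatic) | bd$aromatic | bd$order == 4))
  cn <- (el1 == "C" & el2 == "N") | (el1 == "N" & el2 == "C")
  ms["n_CN_anyorder"] <- sum(cn)
  sizes <- vapply(mol$rings, length, integer(1))
  for (k in 3:12) ms[paste0("n_ring_size_", k)] <- sum(sizes == k)
  ms["n_ring_size_13plus"] <- sum(sizes >= 13)
  ring_has <- function(el) sum(vapply(mol$rings, function(r)
    any(at$element[r] == el), logical(1)))
  ms["n_rings_with_N"] <- ring_has("N")
  ms["n_rings_with_O"] <- ring_has("O")
  ms["n_rings_with_S"] <- ring_has("S")
  ms["n_heteroatoms"] <- sum(heavy & is_heteroatom(at$element))
  ms["n_halogens"] <- sum(at$element %in% .HALOGENS)
  ms["n_charged_atoms"] <- sum(heavy & at$charge != 0)
  attr(ms, "ring_method") <- mol$ring_method
  ms
}

# fragment token for one atom: element, lower-cased when aromatic
.atom_token <- function(mol, a) {
  el <- mol$atoms$element[a]
  if (mol$atoms$aromatic[a]) tolower(el) else el
}

.bond_token <- function(mol, bi) {
  if (mol$bonds$aromatic[bi] || mol$bonds$order[bi] == 4) return("~")
  c("-", "=", "#")[mol$bonds$order[bi]]
}

#' Enumerate canonical linear fragment strings
#'
#' Every simple path of `min_atoms` to `max_atoms` heavy atoms is rendered
#' as an alternating atom-token / bond-token string (aromatic atoms in
#' lower case, bonds as `-`, `=`, `#`, `~`); each undirected path is listed
#' once, as the lexicographically smaller of its two directions.
#'
#' @param mol a perceived `molecule`
#' @param min_atoms,max_atoms path length bounds in atoms (defaults 3 and 8)
#' @param max_paths safety cap on the number of enumerated paths; dense
#'   graphs exceeding it raise an error
#' @return a character vector, one entry per path (duplicates possible when
#'   distinct paths render identically).
#' @export
linear_fragments <- function(mol, min_atoms = 3, max_atoms = 8,
                             max_paths = 1e6) {
  stopifnot(mol$perceived)
  n <- nrow(mol$atoms)
  heavy <- which(!is_hydrogen(mol$atoms$element))
  adj <- adjacency_list(mol)
  lookup <- bond_lookup(mol)
  atom_tok <- vapply(seq_len(n), function(a) .atom_token(mol, a), character(1))
  frags <- character(0)
  count <- 0
  path <- integer(max_atoms)
  toks <- character(2 * max_atoms - 1)
  onpath <- logical(n)
  emit <- function(depth) {
    s <- paste(toks[seq_len(2 * depth - 1)], collapse = "")
    r <- paste(rev(toks[seq_len(2 * depth - 1)]), collapse = "")
    frags[length(frags) + 1] <<- if (s <= r) s else r
  }
  dfs <- function(v, depth) {
    count <<- count + 1
    if (count > max_paths)
      stop("linear_fragments: path enumeration overflow (max_paths exceeded)")
    if (depth >= min_atoms && path[1] < v) emit(depth)
    if (depth == max_atoms) return()
    for (w in adj[[v]]) {
      if (onpath[w] || is_hydrogen(mol$atoms$element[w])) next
      path[depth + 1] <<- w
      toks[2 * depth] <<- .bond_token(mol, bond_index(lookup, n, v, w))
      toks[2 * depth + 1] <<- atom_tok[w]
      onpath[w] <<- TRUE
      dfs(w, depth + 1)
      onpath[w] <<- FALSE
    }
  }
  for (s in heavy) {
    path[1] <- s
    toks[1] <- atom_tok[s]
    onpath[s] <- TRUE
    dfs(s, 1)
    onpath[s] <- FALSE
  }
  frags
}

# 32-bit string hashes from the general-purpose family; doubles carry the
# arithmetic exactly because every intermediate stays below 2^53
.hash_bkdr <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 4294967296
  h
}

.hash_djb <- function(s) {
  h <- 5381
  for (c in utf8ToInt(s)) h <- (h * 33 + c) %% 4294967296
  h
}

#' Hashed 512-bit path fingerprint
#'
#' Each linear fragment string is passed to two independent string hashes
#' (BKDR and DJB variants); each hash selects one position in 1..512 and the
#' corresponding bits are set.  Bits are set idempotently, so hashing each
#' occurrence or each distinct string gives the same fingerprint.
#'
#' @param mol a perceived `molecule`
#' @param min_atoms,max_atoms fragment length bounds, see [linear_fragments()]
#' @return a [bitstring()] of 512 bits.
#' @export
hashed_fingerprint <- function(mol, min_atoms = 3, max_atoms = 8) {
  frags <- unique(linear_fragments(mol, min_atoms, max_atoms))
  fp <- bitstring(512)
  if (!length(frags)) return(fp)
  pos <- unlist(lapply(frags, function(s)
    c(.hash_bkdr(s) %% 512, .hash_djb(s) %% 512)))
  bs_set(fp, unique(pos))
}

#' Dictionary fingerprint
#'
#' Bit `k` (0-based, `k >= 1`) is set when dictionary entry `k` is a
#' substructure of `mol`; bit 0, the least significant bit of the first
#' segment, is set when `mol` is identical (exact match) to some entry, so
#' identity is visible as an odd first segment.  The bitstring length is
#' `1 + <dictionary size>` rounded up to a multiple of 32.
#'
#' @param mol a perceived `molecule`
#' @param dictionary a list of perceived `molecule` fragments (see
#'   [default_dictionary()]); at most 511 entries
#' @return a [bitstring()].
#' @export
dictionary_fingerprint <- function(mol, dictionary) {
  if (length(dictionary) > 511)
    stop("dictionary_fingerprint: dictionary exceeds capacity (511 entries)")
  len <- 32 * ceiling((length(dictionary) + 1) / 32)
  fp <- bitstring(max(len, 32))
  identical_hit <- FALSE
  for (k in seq_along(dictionary)) {
    entry <- dictionary[[k]]
    if (match_mol(entry, mol)$verdict) {
      fp <- bs_set(fp, k)
      if (!identical_hit && match_mol(entry, mol, mode = "exact")$verdict)
        identical_hit <- TRUE
    }
  }
  if (identical_hit) fp <- bs_set(fp, 0)
  fp
}
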