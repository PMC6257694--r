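#' @title Indexed two-stage structure and reaction search
#' @description
#' An in-memory index of compound and reaction records.  Every entry stores
#' the tweaked molfile plus all pre-selection descriptors (molstat counters,
#' hashed fingerprint, dictionary fingerprint, functional-group segments
#' fg01..fg08, and the hashed-fingerprint popcount).  Searches run in two
#' stages: descriptor pre-selection (bitwise subset and counter
#' inequalities, the in-memory equivalent of a relational `&`-mask query)
#' followed by atom-by-atom confirmation of each surviving candidate.
#' Pre-selection is sound: it never drops a record the matcher would
#' accept.
#' @name search_engine
NULL

#' Create an empty search index
#'
#' @param dictionary fragment dictionary for dictionary fingerprints, a
#'   list of perceived molecules (default [default_dictionary()]); pass
#'   `list()` to disable dictionary fingerprints.
#' @return an object of class `mol_index` (environment semantics: indexing
#'   functions mutate it in place).
#' @export
mol_index <- function(dictionary = default_dictionary()) {
  idx <- new.env(parent = emptyenv())
  idx$dictionary <- dictionary
  # dictionary bits usable for sound pre-selection: entries without
  # explicit hydrogens (hydrogen-count constraints do not compose through
  # a substructure chain)
  idx$dict_safe <- vapply(dictionary, function(d)
    all(!is_hydrogen(d$atoms$element)), logical(1))
  idx$compounds <- list()
  idx$reactions <- list()
  class(idx) <- "mol_index"
  idx
}

#' @export
print.mol_index <- function(x, ...) {
  cat(sprintf("<mol_index: %d compound(s), %d reaction(s), %d dictionary entries>\n",
              length(x$compounds), length(x$reactions), length(x$dictionary)))
  invisible(x)
}

.compound_descriptors <- function(mol, dictionary) {
  fp <- hashed_fingerprint(mol)
  fg <- detect_groups(mol)
  dict <- dictionary_fingerprint(mol, dictionary)
  list(mol = mol,
       molstat = compute_molstat(mol),
       ring_method = mol$ring_method,
       fp = fp, fp_segments = bs_segments(fp),
       popcount = bs_popcount(fp),
       dict = dict, dict_segments = bs_segments(dict),
       fg = fg$descriptor, fg_segments = fg$segments)
}

#' Add a structure to the index
#'
#' Perception runs once at indexing time; the stored molfile is written in
#' the tweaked dialect so later searches can skip ring search and
#' aromaticity detection.  All descriptors are computed and stored with the
#' record.
#'
#' @param idx a [mol_index()]
#' @param molfile molfile text (or an already parsed/perceived `molecule`)
#' @param id unique record identifier (default: running number)
#' @return the new record, invisibly.
#' @export
index_structure <- function(idx, molfile, id = NULL) {
  stopifnot(inherits(idx, "mol_index"))
  mol <- if (inherits(molfile, "molecule")) molfile else parse_molfile(molfile)
  mol <- perceive(mol)
  if (is.null(id)) id <- as.character(length(idx$compounds) + 1)
  id <- as.character(id)
  if (!is.null(idx$compounds[[id]]))
    stop(sprintf("index_structure: duplicate id '%s'", id))
  rec <- .compound_descriptors(mol, idx$dictionary)
  rec$id <- id
  rec$molfile <- write_molfile(mol, tweaked = TRUE)
  idx$compounds[[id]] <- rec
  invisible(rec)
}

.cumulative <- function(bitstrings) {
  out <- bitstrings[[1]]
  for (b in bitstrings[-1]) out <- bs_or(out, b)
  out
}

#' Add a reaction to the index
#'
#' Stores cumulative (bitwise-OR) hashed, dictionary and functional-group
#' fingerprints for the reactant side and for the product side.  Molecular
#' statistics are not stored for reactions.
#'
#' @param idx a [mol_index()]
#' @param rxn RXN text or a parsed `reaction`
#' @param id unique identifier
#' @return the new record, invisibly.
#' @export
index_reaction <- function(idx, rxn, id = NULL) {
  stopifnot(inherits(idx, "mol_index"))
  if (!inherits(rxn, "reaction")) rxn <- parse_rxnfile(rxn)
  if (!length(rxn$reactants) || !length(rxn$products))
    stop("index_reaction: a reaction needs at least one reactant and one product")
  if (is.null(id)) id <- as.character(length(idx$reactions) + 1)
  id <- as.character(id)
  if (!is.null(idx$reactions[[id]]))
    stop(sprintf("index_reaction: duplicate id '%s'", id))
  side <- function(mols) {
    mols <- lapply(mols, perceive)
    list(mols = mols,
         fp = .cumulative(lapply(mols, hashed_fingerprint)),
         dict = .cumulative(lapply(mols, dictionary_fingerprint,
                                   dictionary = idx$dictionary)),
         fg = .cumulative(lapply(mols, function(m) detect_groups(m)$descriptor)))
  }
  rec <- list(id = id, reactants = side(rxn$reactants),
              products = side(rxn$products),
              atom_maps = rxn$atom_maps,
              rxn = rxn)
  rec$reactant_fg_segments <- bs_segments(rec$reactants$fg)
  rec$product_fg_segments <- bs_segments(rec$products$fg)
  idx$reactions[[id]] <- rec
  invisible(rec)
}

# stage-1 molstat filter: every query counter must be <= the record's.
# ring-derived counters are skipped when the record's ring set came from
# the SSSR fallback (its counts are not comparable with a SAR query).
.molstat_admits <- function(q, rec) {
  r <- rec$molstat
  keep <- rep(TRUE, length(q))
  if (identical(rec$ring_method, "fallback")) {
    ring_counters <- grepl("^n_ring", names(q)) | names(q) == "n_rings" |
      grepl("^n_rings_with", names(q))
    keep <- !ring_counters
  }
  all(q[keep] <= r[keep])
}

.dict_subset <- function(q, r, safe) {
  # LSB (identity flag) and unsound entries are excluded from screening
  qq <- as.logical(q); rr <- as.logical(r)
  qq[1] <- FALSE
  if (length(safe) && any(!safe)) qq[which(!safe) + 1] <- FALSE
  !any(qq & !rr)
}

#' Two-stage substructure / exact structure search
#'
#' Stage 1 keeps records whose molstat counters dominate the query's, whose
#' hashed fingerprint contains every query bit, and whose dictionary
#' fingerprint contains every (screenable) query bit.  If the query is
#' identical to a dictionary fragment, the corresponding structure bit
#' answers the search directly with no atom-by-atom matching.  Stage 2
#' confirms every surviving candidate with [match_mol()].
#'
#' @param idx a [mol_index()]
#' @param query molfile text or `molecule`
#' @param mode `"substructure"` (default) or `"exact"`
#' @param strict,check_geometry,check_chirality passed to [match_mol()]
#' @return a list: `hits` (character ids), `n_candidates` (records that
#'   survived pre-selection), `n_searched`.
#' @export
substructure_search <- function(idx, query, mode = "substructure",
                                strict = FALSE, check_geometry = FALSE,
                                check_chirality = FALSE) {
  stopifnot(inherits(idx, "mol_index"))
  q <- if (inherits(query, "molecule")) query else parse_molfile(query)
  q <- perceive(q)
  qd <- .compound_descriptors(q, idx$dictionary)
  recs <- idx$compounds

  # identity fast path: query equals a dictionary fragment
  if (mode == "substructure" && !strict && !check_geometry &&
      !check_chirality && bs_get(qd$dict, 0)) {
    k <- which(vapply(seq_along(idx$dictionary), function(i)
      bs_get(qd$dict, i) &&
        match_mol(idx$dictionary[[i]], q, mode = "exact")$verdict,
      logical(1)))[1]
    if (!is.na(k)) {
      hits <- names(recs)[vapply(recs, function(r) bs_get(r$dict, k),
                                 logical(1))]
      return(list(hits = hits, n_candidates = length(hits),
                  n_searched = length(recs), fast_path = TRUE))
    }
  }

  cand <- Filter(function(r)
    .molstat_admits(qd$molstat, r) &&
      bs_subset(qd$fp, r$fp) &&
      .dict_subset(qd$dict, r$dict, idx$dict_safe),
    recs)
  hits <- character(0)
  for (r in cand) {
    if (match_mol(q, r$mol, mode = mode, strict = strict,
                  check_geometry = check_geometry,
                  check_chirality = check_chirality)$verdict)
      hits <- c(hits, r$id)
  }
  list(hits = hits, n_candidates = length(cand), n_searched = length(recs),
       fast_path = FALSE)
}

#' Similarity search by Tanimoto score on hashed fingerprints
#'
#' Pre-selection: per-counter molstat margins and the popcount bound
#' `T(a,b) <= min(p_a,p_b) / max(p_a,p_b)`; neither filter can drop a record
#' whose true score reaches `min_score`.  Survivors are scored with
#' [tanimoto()] and returned sorted by descending score, ties by id.
#'
#' @param idx a [mol_index()]
#' @param query molfile text or `molecule`
#' @param min_score minimum Tanimoto score in \[0, 1\]
#' @param molstat_margin scalar (or per-counter vector) tolerance on
#'   molstat counter differences; default `Inf` disables the filter
#' @return a data frame with columns `id` and `score`.
#' @export
similarity_search <- function(idx, query, min_score = 0,
                              molstat_margin = Inf) {
  stopifnot(inherits(idx, "mol_index"))
  if (min_score < 0 || min_score > 1)
    stop("similarity_search: min_score must lie in [0, 1]")
  q <- if (inherits(query, "molecule")) query else parse_molfile(query)
  q <- perceive(q)
  qs <- compute_molstat(q)
  qfp <- hashed_fingerprint(q)
  qp <- bs_popcount(qfp)
  rows <- list()
  for (r in idx$compounds) {
    if (any(abs(qs - r$molstat) > molstat_margin)) next
    bound <- if (max(qp, r$popcount) == 0) 1 else
      min(qp, r$popcount) / max(qp, r$popcount)
    if (bound < min_score) next
    s <- tanimoto(qfp, r$fp)
    if (s >= min_score)
      rows[[length(rows) + 1]] <- data.frame(id = r$id, score = s,
                                             stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(id = character(0), score = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(-out$score, out$id), , drop = FALSE]
}

#' Functional-group pattern search
#'
#' Returns exactly the records whose stored fg01..fg08 segments satisfy
#' every bitwise-AND mask predicate of the encoded query.  An empty
#' selection matches every record.
#'
#' @param idx a [mol_index()]
#' @param groups selected groups: 0-based bit positions, or group ids /
#'   English names (resolved via [fg_positions()])
#' @return character vector of record ids.
#' @export
functional_group_search <- function(idx, groups) {
  stopifnot(inherits(idx, "mol_index"))
  positions <- if (is.numeric(groups)) as.integer(groups) else fg_positions(groups)
  preds <- mask_predicates(encode_group_query(positions))
  names(idx$compounds)[vapply(idx$compounds, function(r)
    satisfies_masks(r$fg_segments, preds), logical(1))]
}

#' Two-stage reaction substructure search
#'
#' Stage 1 requires the query's cumulative hashed and dictionary reactant
#' bits to be contained in the candidate's cumulative reactant bits, and
#' likewise for products.  Stage 2 requires every query reactant to be a
#' substructure of some candidate reactant and every query product of some
#' candidate product.  With `check_maps`, every pair of query atoms sharing
#' an atom-map class across the two sides must land on a candidate atom
#' pair that also shares a candidate map class, for at least one consistent
#' choice of embeddings.  A query side with no molecules (a half reaction)
#' imposes no constraint for that side.
#'
#' @param idx a [mol_index()]
#' @param rxn RXN text or parsed `reaction`
#' @param check_maps verify atom/atom map consistency
#' @return a list: `hits`, `n_candidates`, `n_searched`.
#' @export
reaction_search <- function(idx, rxn, check_maps = FALSE) {
  stopifnot(inherits(idx, "mol_index"))
  if (!inherits(rxn, "reaction")) rxn <- parse_rxnfile(rxn)
  q_react <- lapply(rxn$reactants, perceive)
  q_prod <- lapply(rxn$products, perceive)
  side_desc <- function(mols) {
    if (!length(mols)) return(NULL)
    list(fp = .cumulative(lapply(mols, hashed_fingerprint)),
         dict = .cumulative(lapply(mols, dictionary_fingerprint,
                                   dictionary = idx$dictionary)))
  }
  qr <- side_desc(q_react); qp <- side_desc(q_prod)
  admits <- function(qside, rside) {
    is.null(qside) ||
      (bs_subset(qside$fp, rside$fp) &&
         .dict_subset(qside$dict, rside$dict, idx$dict_safe))
  }
  cand <- Filter(function(r) admits(qr, r$reactants) && admits(qp, r$products),
                 idx$reactions)
  hits <- character(0)
  for (r in cand) {
    ok <- .reaction_stage2(q_react, q_prod, r, check_maps,
                           atom_maps = rxn$atom_maps)
    if (ok) hits <- c(hits, r$id)
  }
  list(hits = hits, n_candidates = length(cand),
       n_searched = length(idx$reactions))
}

.reaction_stage2 <- function(q_react, q_prod, rec, check_maps, atom_maps) {
  # candidate embeddings of each query molecule into each candidate
  # molecule of the same side
  side_options <- function(qmols, cmols, side) {
    lapply(seq_along(qmols), function(i) {
      opts <- list()
      for (j in seq_along(cmols)) {
        if (!check_maps) {
          if (match_mol(qmols[[i]], cmols[[j]])$verdict)
            opts[[length(opts) + 1]] <- list(mol = j, map = NULL)
        } else {
          ms <- enumerate_mappings(qmols[[i]], cmols[[j]], max_mappings = 200)
          for (m in ms) opts[[length(opts) + 1]] <- list(mol = j, map = m)
        }
      }
      opts
    })
  }
  r_opts <- side_options(q_react, rec$reactants$mols, "reactant")
  p_opts <- side_options(q_prod, rec$products$mols, "product")
  if (any(!vapply(r_opts, length, integer(1))) ||
      any(!vapply(p_opts, length, integer(1)))) return(FALSE)
  if (!check_maps || !nrow(atom_maps)) return(TRUE)

  # map-class pairs of the query that must be preserved
  pairs <- list()
  r_rows <- atom_maps[atom_maps$side == "reactant", , drop = FALSE]
  p_rows <- atom_maps[atom_maps$side == "product", , drop = FALSE]
  for (i in seq_len(nrow(r_rows))) {
    j <- which(p_rows$class == r_rows$class[i])
    for (k in j)
      pairs[[length(pairs) + 1]] <- list(r = r_rows[i, ], p = p_rows[k, ])
  }
  if (!length(pairs)) return(TRUE)

  cand_map_class <- function(side, mol_idx, atom) {
    mols <- if (side == "reactant") rec$reactants$mols else rec$products$mols
    mols[[mol_idx]]$atoms$map[atom]
  }
  # search one consistent assignment of embeddings over all query molecules
  n_r <- length(r_opts); n_p <- length(p_opts)
  choice_r <- integer(n_r); choice_p <- integer(n_p)
  consistent <- function() {
    for (pr in pairs) {
      ro <- r_opts[[pr$r$mol]][[choice_r[pr$r$mol]]]
      po <- p_opts[[pr$p$mol]][[choice_p[pr$p$mol]]]
      img_r <- ro$map[as.character(pr$r$atom)]
      img_p <- po$map[as.character(pr$p$atom)]
      if (is.na(img_r) || is.na(img_p)) return(FALSE)
      cr <- cand_map_class("reactant", ro$mol, img_r)
      cp <- cand_map_class("product", po$mol, img_p)
      if (cr == 0 || cp == 0 || cr != cp) return(FALSE)
    }
    TRUE
  }
  assign_next <- function(k) {
    if (k > n_r + n_p) return(consistent())
    opts <- if (k <= n_r) r_opts[[k]] else p_opts[[k - n_r]]
    for (c in seq_along(opts)) {
      if (k <= n_r) choice_r[k] <<- c else choice_p[k - n_r] <<- c
      if (assign_next(k + 1)) return(TRUE)
    }
    FALSE
  }
  assign_next(1)
}

#' Functional-group search over reactions
#'
#' Tests the cumulative functional-group segments of indexed reactions.
#' Modes: `in_reactants` / `in_products` require every selected bit in the
#' respective cumulative descriptor; `lost` requires every selected bit set
#' on the reactant side and clear on the product side; `created` the
#' reverse.  (Evaluated on cumulative bitstrings: a group present on both
#' sides in different molecules is neither lost nor created.)
#'
#' @param idx a [mol_index()]
#' @param groups positions or group ids/names, as in
#'   [functional_group_search()]
#' @param mode one of `"in_reactants"`, `"in_products"`, `"lost"`,
#'   `"created"`
#' @return character vector of reaction ids.
#' @export
reaction_fg_search <- function(idx, groups,
                               mode = c("in_reactants", "in_products",
                                        "lost", "created")) {
  stopifnot(inherits(idx, "mol_index"))
  mode <- match.arg(mode)
  positions <- if (is.numeric(groups)) as.integer(groups) else fg_positions(groups)
  preds <- mask_predicates(encode_group_query(positions))
  sel <- bs_set(bitstring(256), positions)
  ok <- vapply(idx$reactions, function(r) {
    switch(mode,
      in_reactants = satisfies_masks(r$reactant_fg_segments, preds),
      in_products = satisfies_masks(r$product_fg_segments, preds),
      lost = satisfies_masks(r$reactant_fg_segments, preds) &&
        !any(sel & r$products$fg),
      created = satisfies_masks(r$product_fg_segments, preds) &&
        !any(sel & r$reactants$fg))
  }, logical(1))
  names(idx$reactions)[ok]
}

#' Export a hit list as delimited text
#' @param hits character ids (or the list returned by the search functions)
#' @param scores optional numeric scores aligned with the ids
#' @return a single tab-separated string, one line per hit.
#' @export
format_hitlist <- function(hits, scores = NULL) {
  if (is.list(hits) && !is.null(hits$hits)) hits <- hits$hits
  if (!length(hits)) return("")
  if (is.null(scores))
    paste(sprintf("%s\tT", hits), collapse = "\n")
  else
    paste(sprintf("%s\t%.4f", hits, scores), collapse = "\n")
}
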