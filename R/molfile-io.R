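#' @title MDL molfile, SD file and RXN file input/output
#' @description
#' Readers and writers for the MDL V2000 connection-table family, plus the
#' "tweaked" molfile dialect that persists aromaticity perception inside
#' spec-unused columns so that a stored structure can skip ring search and
#' aromaticity detection when it is read back.
#'
#' Dialect convention: a tweaked file carries the token `CMTWEAK` in the
#' program line of the header, a `1` in the atom-block H0-designator field
#' (columns 52-54, deprecated by the format) for every aromatic atom, and a
#' `1` in the bond-block "not used" field (columns 13-15) for every aromatic
#' bond.  Conforming V2000 readers ignore all three, so the dialect is
#' transparent.
#' @name molfile_io
NULL

MOLGREP_TWEAK_TOKEN <- "CMTWEAK"

.subint <- function(line, from, to) {
  s <- trimws(substr(line, from, to))
  if (s == "" || is.na(s)) return(0L)
  v <- suppressWarnings(as.integer(s))
  if (is.na(v)) 0L else v
}

.subnum <- function(line, from, to) {
  s <- trimws(substr(line, from, to))
  if (s == "") return(0)
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) 0 else v
}

.charge_from_code <- function(code) {
  # atom-block ccc codes; 4 means doublet radical, not a charge
  c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
    `5` = -1L, `6` = -2L, `7` = -3L)[as.character(code)]
}

.code_from_charge <- function(charge) {
  m <- c(`3` = 1L, `2` = 2L, `1` = 3L, `0` = 0L,
         `-1` = 5L, `-2` = 6L, `-3` = 7L)
  code <- m[as.character(charge)]
  ifelse(is.na(code), 0L, code)
}

new_molecule <- function(atoms, bonds, header = c("", "", ""), tweak = FALSE,
                         name = "") {
  structure(list(
    atoms = atoms, bonds = bonds,
    rings = list(), ring_method = NA_character_,
    perceived = FALSE, tweak = tweak,
    header = header, name = name,
    warnings = character(0)
  ), class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule%s: %d atoms, %d bonds%s%s>\n",
              if (nzchar(x$name)) paste0(" ", x$name) else "",
              nrow(x$atoms), nrow(x$bonds),
              if (x$perceived) sprintf(", %d rings, perceived", length(x$rings)) else "",
              if (x$tweak) ", tweaked" else ""))
  invisible(x)
}

#' Parse an MDL V2000 molfile
#'
#' Captures elements, coordinates, charges (atom-block column codes and
#' `M  CHG` property lines, the latter taking precedence and, per the format
#' definition, resetting every atom-block charge when present), isotope mass
#' differences (`M  ISO` likewise), radicals (`M  RAD`), bond orders and
#' wedge/hash stereo marks, and atom-atom map classes.  A file written in the
#' tweaked dialect is recognized by its header token; its stored aromaticity
#' flags are attached so that [perceive()] can skip ring search.
#'
#' @param text molfile content as a single string or a character vector of
#'   lines.
#' @return an object of class `molecule` (not yet perceived unless loaded
#'   from a tweaked file and passed through [perceive()]).
#' @examples
#' mol <- parse_molfile(builtin_molecules()[["benzene"]])
#' nrow(mol$atoms)  # 6
#' @export
parse_molfile <- function(text) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (length(lines) < 4) stop("molfile parse error at line 1: truncated header")
  header <- lines[1:3]
  counts <- lines[4]
  if (grepl("V3000", counts, fixed = TRUE))
    stop("molfile parse error at line 4: V3000 connection tables are not supported")
  n_atoms <- suppressWarnings(as.integer(trimws(substr(counts, 1, 3))))
  n_bonds <- suppressWarnings(as.integer(trimws(substr(counts, 4, 6))))
  if (is.na(n_atoms) || is.na(n_bonds))
    stop("molfile parse error at line 4: malformed counts line")
  if (length(lines) < 4 + n_atoms + n_bonds)
    stop(sprintf("molfile parse error at line %d: truncated atom/bond block",
                 length(lines) + 1))
  tweak <- grepl(MOLGREP_TWEAK_TOKEN, header[2], fixed = TRUE)

  atoms <- data.frame(
    element = character(n_atoms), charge = integer(n_atoms),
    isotope = integer(n_atoms), radical = integer(n_atoms),
    x = numeric(n_atoms), y = numeric(n_atoms), z = numeric(n_atoms),
    map = integer(n_atoms), aromatic = logical(n_atoms),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n_atoms)) {
    ln <- lines[4 + i]
    el <- trimws(substr(ln, 32, 34))
    if (el == "")
      stop(sprintf("molfile parse error at line %d: missing element symbol", 4 + i))
    atoms$element[i] <- el
    atoms$x[i] <- .subnum(ln, 1, 10)
    atoms$y[i] <- .subnum(ln, 11, 20)
    atoms$z[i] <- .subnum(ln, 21, 30)
    atoms$isotope[i] <- .subint(ln, 35, 36)
    code <- .subint(ln, 37, 39)
    atoms$charge[i] <- .charge_from_code(code)
    atoms$radical[i] <- if (code == 4L) 2L else 0L
    atoms$aromatic[i] <- tweak && .subint(ln, 52, 54) == 1L
    atoms$map[i] <- .subint(ln, 61, 63)
  }

  bonds <- data.frame(
    a1 = integer(n_bonds), a2 = integer(n_bonds),
    order = integer(n_bonds), stereo = integer(n_bonds),
    aromatic = logical(n_bonds), stringsAsFactors = FALSE
  )
  for (i in seq_len(n_bonds)) {
    ln <- lines[4 + n_atoms + i]
    a1 <- .subint(ln, 1, 3); a2 <- .subint(ln, 4, 6)
    if (a1 < 1 || a2 < 1 || a1 > n_atoms || a2 > n_atoms || a1 == a2)
      stop(sprintf("molfile parse error at line %d: bad bond atom indices",
                   4 + n_atoms + i))
    bonds$a1[i] <- a1; bonds$a2[i] <- a2
    bonds$order[i] <- .subint(ln, 7, 9)
    bonds$stereo[i] <- .subint(ln, 10, 12)
    bonds$aromatic[i] <- tweak && .subint(ln, 13, 15) == 1L
  }

  # properties block: M  CHG / M  ISO / M  RAD supersede the atom block
  prop <- lines[-seq_len(4 + n_atoms + n_bonds)]
  apply_pairs <- function(ln, col) {
    tok <- strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]]
    tok <- suppressWarnings(as.integer(tok))
    n <- tok[1]
    for (k in seq_len(n)) {
      idx <- tok[2 * k]; val <- tok[2 * k + 1]
      if (!is.na(idx) && idx >= 1 && idx <= n_atoms) atoms[[col]][idx] <<- val
    }
  }
  if (any(grepl("^M  (CHG|RAD)", prop))) {
    atoms$charge <- 0L; atoms$radical <- 0L
  }
  if (any(grepl("^M  ISO", prop))) atoms$isotope <- 0L
  for (ln in prop) {
    if (startsWith(ln, "M  CHG")) apply_pairs(ln, "charge")
    else if (startsWith(ln, "M  ISO")) apply_pairs(ln, "isotope")
    else if (startsWith(ln, "M  RAD")) apply_pairs(ln, "radical")
  }

  new_molecule(atoms, bonds, header = header, tweak = tweak,
               name = trimws(header[1]))
}

#' Write a molecule as an MDL V2000 molfile
#'
#' @param mol a `molecule`; must be perceived when `tweaked = TRUE` so that
#'   the aromaticity flags to be persisted exist.
#' @param tweaked write the tweaked dialect (see [molfile_io]) instead of a
#'   plain V2000 file.
#' @return the molfile as a single string.
#' @export
write_molfile <- function(mol, tweaked = FALSE) {
  stopifnot(inherits(mol, "molecule"))
  if (tweaked && !mol$perceived)
    stop("write_molfile: molecule must be perceived before tweaked output")
  n_atoms <- nrow(mol$atoms); n_bonds <- nrow(mol$bonds)
  if (n_atoms > 999 || n_bonds > 999)
    stop("write_molfile: V2000 capacity exceeded (>999 atoms or bonds)")
  prog <- sprintf("  molgrep %s", if (tweaked) MOLGREP_TWEAK_TOKEN else "")
  header <- c(mol$name, prog, "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_atoms, n_bonds)
  atom_lines <- vapply(seq_len(n_atoms), function(i) {
    a <- mol$atoms[i, ]
    ar <- if (tweaked && isTRUE(a$aromatic)) 1L else 0L
    # fields after the symbol: dd ccc sss hhh bbb vvv HHH rrr iii mmm nnn eee
    # (HHH carries the tweak flag, mmm the atom-atom map class)
    sprintf("%10.4f%10.4f%10.4f %-3s%2d%3d%3d%3d%3d%3d%3d%3d%3d%3d%3d%3d",
            a$x, a$y, a$z, a$element, 0L, .code_from_charge(a$charge),
            0L, 0L, 0L, 0L, ar, 0L, 0L, a$map, 0L, 0L)
  }, character(1))
  bond_lines <- vapply(seq_len(n_bonds), function(i) {
    b <- mol$bonds[i, ]
    ar <- if (tweaked && isTRUE(b$aromatic)) 1L else 0L
    sprintf("%3d%3d%3d%3d%3d  0  0", b$a1, b$a2, b$order, b$stereo, ar)
  }, character(1))
  props <- character(0)
  chg <- which(mol$atoms$charge != 0L)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      props <- c(props, paste0(
        sprintf("M  CHG%3d", length(grp)),
        paste0(sprintf(" %3d %3d", grp, mol$atoms$charge[grp]), collapse = "")))
    }
  }
  iso <- which(mol$atoms$isotope != 0L)
  if (length(iso)) {
    for (grp in split(iso, ceiling(seq_along(iso) / 8))) {
      props <- c(props, paste0(
        sprintf("M  ISO%3d", length(grp)),
        paste0(sprintf(" %3d %3d", grp, mol$atoms$isotope[grp]), collapse = "")))
    }
  }
  rad <- which(mol$atoms$radical != 0L)
  if (length(rad)) {
    for (grp in split(rad, ceiling(seq_along(rad) / 8))) {
      props <- c(props, paste0(
        sprintf("M  RAD%3d", length(grp)),
        paste0(sprintf(" %3d %3d", grp, mol$atoms$radical[grp]), collapse = "")))
    }
  }
  paste(c(header, counts, atom_lines, bond_lines, props, "M  END"),
        collapse = "\n")
}

#' Read an SD file into (molecule, data fields) records
#'
#' Records are delimited by `$$$$`.  Data fields follow the `> <name>` header
#' convention; each field's value is the text up to the next blank line.
#'
#' @param text SD file content (single string or lines) or a file path.
#' @param tolerant if `TRUE` a record that fails to parse is reported as a
#'   warning and skipped; the default is fail-fast.
#' @return a list of `list(mol = <molecule>, fields = <named character>)`.
#' @export
read_sdf <- function(text, tolerant = FALSE) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  # trim trailing blank lines
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (!length(lines)) return(list())
  ends <- which(trimws(lines) == "$$$$")
  if (!length(ends) || ends[length(ends)] != length(lines))
    stop(sprintf("SD file error: record %d missing '$$$$' terminator",
                 length(ends) + 1))
  starts <- c(1, head(ends, -1) + 1)
  out <- list()
  for (r in seq_along(starts)) {
    rec <- lines[starts[r]:(ends[r] - 1)]
    parsed <- tryCatch({
      mend <- which(startsWith(rec, "M  END"))
      if (!length(mend)) stop("no 'M  END' line")
      mol <- parse_molfile(rec[seq_len(mend[1])])
      fields <- character(0)
      i <- mend[1] + 1
      while (i <= length(rec)) {
        if (startsWith(rec[i], ">")) {
          nm <- sub(".*<([^>]*)>.*", "\\1", rec[i])
          val <- character(0)
          i <- i + 1
          while (i <= length(rec) && nzchar(trimws(rec[i]))) {
            val <- c(val, rec[i]); i <- i + 1
          }
          fields[nm] <- paste(val, collapse = "\n")
        }
        i <- i + 1
      }
      list(mol = mol, fields = fields)
    }, error = function(e) e)
    if (inherits(parsed, "error")) {
      msg <- sprintf("SD record %d: %s", r, conditionMessage(parsed))
      if (tolerant) warning(msg) else stop(msg)
    } else {
      out[[length(out) + 1]] <- parsed
    }
  }
  out
}

#' Write molecules (with optional data fields) as an SD file
#' @param mols list of `molecule` objects
#' @param fields optional list of named character vectors, one per molecule
#' @param tweaked write each record in the tweaked dialect
#' @export
write_sdf <- function(mols, fields = NULL, tweaked = FALSE) {
  recs <- vapply(seq_along(mols), function(i) {
    block <- write_molfile(mols[[i]], tweaked = tweaked)
    fl <- if (!is.null(fields) && length(fields) >= i) fields[[i]] else NULL
    ftxt <- if (length(fl))
      paste(vapply(names(fl), function(nm)
        sprintf(">  <%s>\n%s\n", nm, fl[[nm]]), character(1)), collapse = "\n")
    else ""
    paste0(block, "\n", ftxt, "$$$$")
  }, character(1))
  paste0(paste(recs, collapse = "\n"), "\n")
}

#' Parse an MDL RXN file
#'
#' @param text RXN content as a single string or character lines.
#' @return an object of class `reaction`: `reactants` and `products` (lists
#'   of `molecule`), plus `atom_maps`, a data frame with one row per mapped
#'   atom (`side` is "reactant" or "product", `mol` the 1-based molecule
#'   index on that side, `atom` the atom index, `class` the map class).
#' @export
parse_rxnfile <- function(text) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (!length(lines) || !startsWith(lines[1], "$RXN"))
    stop("RXN parse error at line 1: missing '$RXN' header")
  if (length(lines) < 5) stop("RXN parse error: truncated header")
  counts <- lines[5]
  n_r <- suppressWarnings(as.integer(trimws(substr(counts, 1, 3))))
  n_p <- suppressWarnings(as.integer(trimws(substr(counts, 4, 6))))
  if (is.na(n_r) || is.na(n_p))
    stop("RXN parse error at line 5: malformed reactant/product counts")
  mol_starts <- which(startsWith(lines, "$MOL"))
  if (length(mol_starts) != n_r + n_p)
    stop(sprintf("RXN parse error: counts line declares %d molecules, found %d",
                 n_r + n_p, length(mol_starts)))
  mol_ends <- c(mol_starts[-1] - 1, length(lines))
  mols <- lapply(seq_along(mol_starts), function(i) {
    block <- lines[(mol_starts[i] + 1):mol_ends[i]]
    mend <- which(startsWith(block, "M  END"))
    if (!length(mend))
      stop(sprintf("RXN parse error: embedded molfile %d lacks 'M  END'", i))
    parse_molfile(block[seq_len(mend[1])])
  })
  rxn <- structure(list(
    reactants = mols[seq_len(n_r)],
    products = if (n_p) mols[n_r + seq_len(n_p)] else list()
  ), class = "reaction")
  rxn$atom_maps <- reaction_atom_maps(rxn)
  rxn
}

reaction_atom_maps <- function(rxn) {
  rows <- list()
  collect <- function(mols, side) {
    for (i in seq_along(mols)) {
      mapped <- which(mols[[i]]$atoms$map > 0)
      for (a in mapped)
        rows[[length(rows) + 1]] <<- data.frame(
          side = side, mol = i, atom = a,
          class = mols[[i]]$atoms$map[a], stringsAsFactors = FALSE)
    }
  }
  collect(rxn$reactants, "reactant")
  collect(rxn$products, "product")
  if (!length(rows))
    return(data.frame(side = character(0), mol = integer(0),
                      atom = integer(0), class = integer(0)))
  do.call(rbind, rows)
}

#' @export
print.reaction <- function(x, ...) {
  cat(sprintf("<reaction: %d reactant(s) -> %d product(s), %d mapped atoms>\n",
              length(x$reactants), length(x$products), nrow(x$atom_maps)))
  invisible(x)
}

#' Write a reaction as an MDL RXN file
#' @param rxn a `reaction`
#' @param tweaked write embedded molfiles in the tweaked dialect
#' @export
write_rxnfile <- function(rxn, tweaked = FALSE) {
  blocks <- vapply(c(rxn$reactants, rxn$products), function(m)
    paste0("$MOL\n", write_molfile(m, tweaked = tweaked)), character(1))
  paste(c("$RXN", "", "  molgrep", "",
          sprintf("%3d%3d", length(rxn$reactants), length(rxn$products)),
          blocks), collapse = "\n")
}

#' Read an RD file (reaction + data records)
#'
#' Extracts each embedded `$RXN` block and the `$DTYPE`/`$DATUM` field pairs
#' of its record.
#' @param text RD file content or a path.
#' @return a list of `list(rxn = <reaction>, fields = <named character>)`.
#' @export
read_rdfile <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  starts <- which(startsWith(lines, "$RFMT"))
  if (!length(starts)) return(list())
  ends <- c(starts[-1] - 1, length(lines))
  lapply(seq_along(starts), function(i) {
    rec <- lines[starts[i]:ends[i]]
    rxn_start <- which(startsWith(rec, "$RXN"))[1]
    if (is.na(rxn_start)) stop(sprintf("RD record %d: no $RXN block", i))
    dtypes <- which(startsWith(rec, "$DTYPE"))
    rxn_end <- if (length(dtypes)) dtypes[1] - 1 else length(rec)
    rxn <- parse_rxnfile(rec[rxn_start:rxn_end])
    fields <- character(0)
    for (d in dtypes) {
      nm <- trimws(sub("^\\$DTYPE", "", rec[d]))
      if (d + 1 <= length(rec) && startsWith(rec[d + 1], "$DATUM"))
        fields[nm] <- trimws(sub("^\\$DATUM", "", rec[d + 1]))
    }
    list(rxn = rxn, fields = fields)
  })
}
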