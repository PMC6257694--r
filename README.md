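# molgrep

Functional-group perception and two-stage chemical structure search in R.

Small-molecule databases answer substructure queries with a classic
two-stage process: a cheap *pre-selection* over precomputed descriptors
discards most of the collection, and an atom-by-atom *subgraph-isomorphism*
check confirms the survivors.  `molgrep` is a self-contained engine for that
workflow, aimed at chemists and tool builders who want an inspectable,
scriptable implementation of every stage:

* **Molfile I/O** — MDL V2000 molfiles, SD files, RXN/RD reaction files,
  plus a "tweaked" molfile dialect that stores aromaticity perception in
  spec-unused columns (a `CMTWEAK` token in the header's program line, a `1`
  in the atom block's deprecated H0-designator field for aromatic atoms, and
  a `1` in the bond block's unused field for aromatic bonds), invisible to
  conforming readers but letting stored structures skip ring search on
  re-use.
* **Perception** — the set of all rings (every simple cycle up to 26 atoms,
  with a smallest-set-of-smallest-rings fallback for condensed systems),
  Hückel 4n+2 aromaticity with a per-atom π-contribution table (1 for an
  endocyclic double bond, 2 for a furan-type lone pair or a carbanion, 0 for
  a carbocation or a pyridone-type exocyclic C=O, which does not interrupt
  conjugation), and hybridization subtypes (sp/sp²/sp³/aromatic).
* **Descriptors** — discrete "molstat" counters (atoms, bonds, rings by
  size, C–O/C=O/C–N fragments, heteroatom contacts, ...); a 512-bit hashed
  fingerprint where every linear path of 3–8 atoms sets two bits chosen by
  two independent string hashes; and a dictionary fingerprint with one bit
  per ring-system fragment found as a substructure, whose least significant
  bit (an odd first segment) flags exact identity with a dictionary entry.
* **Functional groups** — a rule-based classifier for 70+ groups (ester,
  amide and its sub-classes, lactam, amidine, amines with the classic
  exclusion rules, sulfonamide, acetal, halides by element and aromaticity,
  ...) written into a fixed-position 256-bit descriptor stored as eight
  unsigned 32-bit segments `fg01..fg08`, queryable with bitwise-AND mask
  predicates of the form `fg_k & mask = mask`.
* **Matching** — recursive atom-by-atom comparison with reference-atom
  selection (branching/heteroatom heuristic or Morgan canonical ranks),
  substructure and exact modes, strict (subtype-matching) mode, explicit
  hydrogens as hydrogen-count constraints, and optional E/Z and R/S
  consistency checks from 2D wedges or 3D coordinates.
* **Search engine** — an in-memory index holding each record's tweaked
  molfile and all descriptors; substructure, similarity (Tanimoto,
  `|A∧B|/|A∨B|`), functional-group, and reaction searches, the latter with
  cumulative (bitwise-OR) fingerprints per reaction side, atom-map
  consistency checking, and lost/created group modes.

Pre-selection is *sound by construction*: every descriptor filter is
monotone under the substructure relation, so stage 1 never discards a
record the matcher would accept.  The test suite proves this against
brute-force oracles on thousands of seeded random molecules.

## A worked example

```r
library(molgrep)
mols <- builtin_molecules()                 # named V2000 molfile texts

mol <- perceive(parse_molfile(mols[["diazepam"]]))
mol
#> <molecule: 20 atoms, 22 bonds, 4 rings, perceived>

detect_groups(mol)
#> <functional groups: 7 detected>
#>   aromatic
#>   heterocycle
#>   amide
#>   tertiary carboxamide
#>   lactam
#>   imine
#>   aryl chloride
detect_groups(mol)$segments                 # fg01..fg08 column values
#> [1] 209715203      2048         8         0         0         0         0         0

encode_group_query(c(3, 33, 38))            # a three-group query pattern
#> [1]  8 66  0  0  0  0  0  0
mask_predicates(encode_group_query(c(3, 33, 38)))
#>   segment mask      # i.e. WHERE (fg01 & 8 = 8) AND (fg02 & 66 = 66)
#> 1       1    8
#> 2       2   66

idx <- mol_index()
for (nm in c("caffeine", "theophylline", "diazepam", "toluene", "sulfanilamide"))
  index_structure(idx, mols[[nm]], id = nm)

substructure_search(idx, mols[["theophylline"]])[c("hits", "n_candidates")]
#> $hits
#> [1] "caffeine"     "theophylline"   # theophylline is caffeine minus one N-methyl
#> $n_candidates
#> [1] 2                               # pre-selection already excluded the rest

functional_group_search(idx, "lactam")
#> [1] "caffeine"     "theophylline" "diazepam"

similarity_search(idx, mols[["caffeine"]], min_score = 0.3)
#>             id     score
#> 1     caffeine 1.0000000
#> 2 theophylline 0.9281046
```

The first segment value `209715203` decodes as the set bits of the detected
groups in `fg01`; the pattern-query segments `8` and `66` come from global
bit positions {3, 33, 38} (2³ = 8 in segment 1; 2¹ + 2⁶ = 66 in segment 2).

A command-line wrapper with `analyze`, `match`, `index` and `search`
subcommands is installed at `inst/cli/molgrep` (see `?molgrep_run`);
`match needle.mol hay1.mol hay2.mol` prints one `ordinal:T|F` line per
candidate.

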