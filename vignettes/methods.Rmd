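---
title: "Perception, descriptors and two-stage search: the methods behind molgrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perception, descriptors and two-stage search: the methods behind molgrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molgrep)
```

`molgrep` implements the full pipeline of a searchable small-molecule
database: file parsing, molecular perception, descriptor generation,
atom-by-atom matching, and a two-stage (pre-select, then confirm) search
layer for structures and reactions.  This vignette explains the models and
conventions behind each stage, the parameters that matter, and the design
choices made where several defensible options existed.

## 1. Perception

### Ring sets

The default ring set is the *set of all rings* (SAR): every simple cycle of
the molecular graph with at most `max_ring_size` atoms (default 26, which
comfortably exceeds the largest ring size the molstat counters distinguish,
"13 or more").  Enumeration is canonical — each cycle is discovered exactly
once, anchored at its lowest-index atom with a fixed traversal direction —
so ring lists are deterministic.

Highly condensed polycycles have exponentially many simple cycles (cubane
already has 28).  When the enumeration would exceed `ring_budget` (default
1024 cycles), the SAR is abandoned and a *smallest set of smallest rings*
(SSSR) cycle basis is computed instead: Horton-style candidate cycles from
per-vertex BFS trees, greedily accepted smallest-first under GF(2) linear
independence of their edge-incidence vectors, until the cyclomatic number
of the graph is reached.  The budget is the operational definition of
"highly condensed"; 1024 is far above anything drug-like, so the fallback
is an escape hatch, not a routine path.  Every fallback ring is also a SAR
cycle, which the tests verify on cubane.

### Aromaticity

Each ring is tested against the Hückel rule.  Every ring atom must be able
to contribute a p orbital; the electron count must be 4n+2 (2, 6, 10, ...).
The contribution table:

| ring atom                                              | π electrons |
|--------------------------------------------------------|-------------|
| endocyclic double (or input-aromatic) bond             | 1           |
| heteroatom (N, O, S, P, Se, As) with a free pair       | 2           |
| carbanion centre                                       | 2           |
| carbocation centre                                     | 0           |
| exocyclic double bond to a terminal atom (C=O, C=C)    | 0, conjugation intact |
| exocyclic double bond into another ring                | 1           |
| saturated carbon                                       | — (breaks conjugation) |

The "0 but conjugation intact" row is what makes 2- and 4-pyridone
aromatic; the "into another ring" row keeps fused aromatics invariant under
the choice of Kekulé structure (in one Kekulé form of naphthalene the
fusion-adjacent atoms have their formal double bond pointing into the
neighbouring ring).  Charged-ring species (tropylium, cyclopentadienide)
follow directly from the carbocation/carbanion rows.  For rings drawn with
input-aromatic (order 4) bonds, a heteroatom counts as pyrrole-type (2
electrons) when it carries three sigma connections or a hydrogen, and
pyridine-type (1) otherwise.

An atom or bond is flagged aromatic when it lies on at least one aromatic
ring.  Aromaticity therefore never depends on which Kekulé structure the
file happened to contain — the suite checks bit-identical flags for both
benzene Kekulé variants.

### Subtypes and hydrogens

After aromaticity, each atom receives a hybridization subtype: `sp` with a
triple bond or two double bonds, `ar` on an aromatic ring, `sp2` with a
double or aromatic bond, `sp3` otherwise.  Implicit hydrogen counts come
from fixed standard valence lists (C 4; N 3,5; O 2; S 2,4,6; P 3,5;
halogens 1), charge-adjusted (+charge for heteroatoms, −|charge| for
carbon), floored at zero.  A bond-order sum no standard valence can absorb
attaches a warning to the molecule rather than failing perception —
databases contain odd valence states, and a warning-bearing record can
still be indexed.

### Tweaked molfiles

Perception results can be persisted inside a V2000 file without breaking
other software: aromatic atoms get a `1` in the deprecated H0-designator
field of the atom block, aromatic bonds a `1` in the "not used" bond-block
field, and the header's program line carries the token `CMTWEAK`.  A
conforming reader ignores all three (verified against an independent SDF
parser in the tests); `molgrep` itself recognizes the token and skips
aromaticity detection when re-reading, reproducing exactly the flags a full
perception pass would compute (also verified fixture-by-fixture).

## 2. Descriptors

### Molstat counters

Thirty-odd discrete counters (atom, bond and ring counts, ring sizes 3–12
and 13+, rings containing N/O/S, carbon hybridization and heteroatom-contact
counts, C–O/C=O/C–N fragment counts, heteroatoms, halogens, charged atoms)
support pre-selection with the filter *query counter ≤ record counter*.
For that filter to be *complete* — never dropping a true substructure — every
counter must be monotone when atoms or bonds are added around a core.  Three
definitions are deliberately cumulative for this reason: the
heteroatom-contact counters count carbons with *at least* 1/2/3 heteroatom
neighbours; perceived aromatic C~O bonds count under both the single- and
the double-bond C–O counters; and the sp² counter counts carbons bearing at
least one double or aromatic bond (an sp carbon with a double bond
included — deleting its triple-bond branch must not let it escape the
count).  Ring-derived counters are compared only between records whose ring
sets were computed the same way; a record indexed through the SSSR fallback
skips them.

### Hashed path fingerprints

Every linear path of 3–8 heavy atoms is rendered as an alternating
atom-token/bond-token string — element symbols, lower-cased on aromatic
atoms; `-`, `=`, `#` for localized bonds and `~` for aromatic bonds — and
canonicalized as the lexicographically smaller of its two reading
directions.  Two independent 32-bit string hashes (the BKDR 131-multiplier
and DJB 33-multiplier variants of the classic general-purpose family) each
select one position in 1..512 per fragment; both bits are set.  Bits are
set idempotently, so hashing occurrences versus distinct strings is
indistinguishable.  Path enumeration is capped at 10⁶ paths per molecule
with an explicit error; no chemically reasonable input approaches the cap.

Over 500 generated drug-like molecules the mean bit density lands around
0.4 — the acceptance band used in the tests is 0.20–0.50, a property check
on a synthetic population rather than a reproduction of any measured
corpus value.

### Dictionary fingerprints

A fragment dictionary (by default 24 common carbo- and heterocyclic ring
systems, exchangeable) yields one bit per entry found as a substructure of
the molecule, plus an identity flag in the least significant bit — an odd
first segment means the molecule *is* one of the dictionary fragments, and
a query with that flag can be answered from stored bits alone, with no
atom-by-atom matching at all.

### Matching semantics and screening soundness

Matching compares atoms on element, charge and aromatic flag (plus
hybridization subtype in strict mode) and bonds on bond class: aromatic
matches aromatic, otherwise orders must be equal.  This pairing of matcher
and fingerprint tokens is deliberate.  If a plain single bond in the query
could match an aromatic bond in the candidate (a rule some systems allow),
then fragments of the query could be absent from the candidate's
fingerprint — a query path ending on what the candidate perceives as an
aromatic atom would hash `O-C-C` while the candidate only contains
`O-C-c` — and pure bitwise-AND pre-selection would silently lose true hits.
With bond classes and atom aromaticity matched exactly, every query path
maps onto an identically-rendered candidate path, and the subset test on
fingerprints is provably sound.  The same reasoning excludes two things
from dictionary-bit screening: the identity flag (identity does not survive
embedding into a larger molecule) and any dictionary entry carrying
explicit hydrogens (a hydrogen-count *minimum* does not compose through a
chain of embeddings).  Functional-group bits are never used to screen
substructure or reaction-substructure queries at all — a group can be
present in a fragment yet absent from its superstructure (an alcohol
etherified away), so those bits are only the *subject* of explicit
functional-group queries.

Explicit hydrogens in a query are constraints: the matched heavy atom must
carry at least that many hydrogens (explicit plus implicit).  Exact mode
requires equal heavy-atom counts, equal bond multisets, and equal charges,
isotopes and per-atom hydrogen totals.  Charges must agree in both modes by
default; a `charge_agnostic` flag relaxes uncharged query atoms.

### Stereochemistry

E/Z consistency is evaluated per mapped non-ring double bond from 2D
coordinates: the lowest-index heavy substituent on each side defines a sign
(which side of the double-bond axis it lies on), and the product of the two
signs must agree between query and candidate.  R/S consistency uses the
sign of the signed tetrahedron volume over three mapped neighbours of a
candidate stereocentre, with 2D wedges lifting atoms out of plane (wedge
up = toward the viewer = +z; a wedge pointing to an unmapped hydrogen
displaces the centre instead).  Parities are compared across the mapping —
no CIP naming is performed — and centres whose mapped neighbours are not
pairwise distinguishable by element and charge are skipped, so symmetric
centres can never cause a spurious rejection.  Degenerate geometry
(all-zero coordinates, no wedges) makes a feature silently unchecked rather
than a mismatch.

## 3. The search engine

Each indexed record stores the tweaked molfile and all descriptors (the
functional-group descriptor as eight unsigned 32-bit segments, mirroring a
relational `fg01..fg08` column layout; the store itself is in-memory, with
the CLI persisting indexes via R serialization at run time).  Substructure
search pre-selects on molstat dominance plus hashed- and dictionary-bit
subsets, then confirms candidates with the matcher; similarity search
pre-filters on per-counter margins and the popcount bound
`T(a,b) ≤ min(p_a, p_b) / max(p_a, p_b)` before computing Tanimoto scores;
functional-group search evaluates the mask predicates exactly.  Reaction
records hold cumulative (bitwise-OR) fingerprints per side; reaction
substructure search screens on the hashed and dictionary cumulatives,
confirms every query reactant against some candidate reactant (and likewise
products), and can additionally require atom-map consistency: every query
atom pair sharing a map class across the two sides must land on a candidate
pair sharing a candidate map class, for at least one consistent choice of
embeddings.  The lost/created group modes are evaluated on the cumulative
bitstrings, so a group present on both sides — even in different
molecules — is neither lost nor created; that is the schema-level semantics
of cumulative descriptors, stated here deliberately.

## 4. The synthetic-molecule generator

Property tests need arbitrarily many valence-correct molecules with known
substructure relationships.  `generate_molecule(seed)` grows a connected
skeleton atom-by-atom (uniform attachment among atoms with free valence),
closes a Poisson-distributed number of rings (mean 2.5, ring sizes 3–7 by
construction of the distance window), upgrades bonds to double (p = 0.15)
or triple (p = 0.01) where valence allows, and rarely (p = 0.02) places one
formal charge.  The default profile — 10–40 heavy atoms, ~70 % carbon, N
and O at 12 % each, S and halogens in small amounts, two to three
independent cycles — emulates a drug-like population.  Halogens are kept
terminal and appended after the skeleton so generation can never paint
itself into a valence corner; element placement is therefore slightly
biased toward heteroatoms at the periphery, which is acceptable for a test
generator and documented here.  Identical seeds give byte-identical
molfiles.

`extract_needle()` deletes random terminal heavy atoms but skips any
deletion that would change the aromaticity flags of the remaining atoms or
bonds (removing a pyridone's exocyclic oxygen would de-aromatize the ring
and legitimately change the match verdict), so extracted needles are
guaranteed substructures with a `TRUE` verdict — the foundation of the
screening-soundness and oracle-equivalence suites.

What the generator does *not* emulate: realistic functional-group
frequencies, synthetic accessibility, stereochemistry, or 2D/3D geometry
(coordinates are zero, so stereo checks are exercised only by the curated
fixtures).  Passing property tests on this population demonstrates
structural correctness of the algorithms, not chemical realism of any
statistic computed from real databases.

## 5. Problem sizes in the test suite

The suite runs 1,400 matcher-versus-oracle verdict comparisons (needles up
to 8 atoms, haystacks up to 14, against an independent brute-force
backtracking oracle), 500+ constructed needle/haystack pairs for screening
soundness, a 200-record index compared against exhaustive matching for all
four search types, a 200-record analog index for the functional-group
superset property, and 500 molecules for the fingerprint-density band —
about two and a half minutes end to end.  These sizes were chosen to
exercise every code path with comfortable statistical coverage while
keeping the suite fast enough to run on every change.

## 6. Known limitations

* No query-atom/bond language (SMARTS-like wildcards), R-groups, atom
  lists, or V3000 connection tables.
* Tautomers are not enumerated; groups and aromaticity are assigned on the
  literal connection table.
* Aromaticity of rings above `max_ring_size` is not considered.
* R/S checking compares parities at centres with three mapped,
  distinguishable heavy neighbours; centres distinguishable only through
  larger substituent trees are skipped (conservatively: never a false
  rejection).
* The functional-group registry holds 71 groups — all classes discussed in
  the documentation plus the common families; it is a frozen, documented
  numbering, not a reproduction of any external catalogue's positions.
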