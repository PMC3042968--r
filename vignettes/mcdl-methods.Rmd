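---
title: "Canonical MCDL descriptors with stereochemistry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical MCDL descriptors with stereochemistry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdl)
```

## The notation

The Modular Chemical Descriptor Language (MCDL) is a linear chemical
notation built from semicolon-separated modules. Two modules identify the
constitution of a molecule uniquely:

* the **composition module** lists *structural fragments* — one
  non-terminal ("core") atom together with its degree-1 ("terminal")
  neighbors — as labels such as `CHH`, `CBrHH` or `SO`, sorted by ASCII
  code and collapsed with multiplicity prefixes (`2OH`);
* the **connectivity module** numbers the fragments `1..n` consistently
  with the composition order and records, for each fragment, the ascending
  list of higher-numbered bonded fragments (`[2,3,5,6;4;;;7]`).

Because many numberings respect the composition order, the package
searches all of them and keeps the minimal connectivity serialization
under a lexicographic order in which an exhausted list sorts before a
longer one. Every numbering achieving that minimum — the *constitutionally
equivalent set* — is retained, because the stereochemical modules are
selected by a second comparison across exactly that set.

Two optional modules carry stereochemistry:

* `{SA:center,top,bottom,left,right}` describes a tetrahedral (or
  lone-pair) center as a Fischer projection: horizontal neighbors point
  toward the viewer, vertical ones away; the highest-priority substituent
  sits on top and the second-highest at the bottom, and the remaining two
  are placed left/right so the drawn configuration is preserved — only
  even numbers of position swaps are allowed when rearranging.
* `{SB:x1dx2,n1,n2,n3,n4}` describes a double bond between fragments
  `x1 < x2`: `n1` is the higher-priority connection to `x1`, `n2` the
  connection to `x2` on the same side of the bond as `n1`, `n4` and `n3`
  the remaining connections to `x1` and `x2`.

Token priority is total: the *dummy* substituent (an electron pair or a
missing sp2 neighbor, serialized as an empty field) outranks everything,
fragments (by ascending rank) outrank terminal atoms, and terminal atoms
compare by ASCII symbol. For molecules with several stereogenic units the
entries are concatenated (SA by center rank, SB by ascending `x1,x2`), and
for every equivalent numbering scheme the resulting token stream is
compared position by position; the stream winning at the first difference
is the canonical descriptor. Atomic units precede double-bond units in the
stream, which realizes the rule that atoms outrank bonds with a single
lexicographic pass — this reproduces the reference selections for the
meso-tartaric and hexadiene cases, and needs no separate iteration for
mixed stereogenic molecules.

## Perception from coordinates

Stereogenic units are detected topologically. Each substituent branch is
identified by `branch_hash()`: the subgraph reached through a neighbor
(with the center deleted) is refined iteratively — element and degree
first, then neighbor hashes with bond orders, for as many rounds as the
branch has atoms — and folded into a fixed 64-bit-style value. An atom
with four pairwise-distinct branches is a stereocenter; a three-coordinate
sulfur with three distinct branches is a lone-pair center and receives a
dummy substituent. Full-depth refinement deliberately distinguishes
branches that differ only away from the center (ethyl vs propyl), a known
blind spot of first-shell comparisons. Acyclic double bonds are stereogenic
when each end's substituents hash differently; ring double bonds and ends
with two identical branches are excluded.

Configurations come from geometry:

* **Atomic parity** follows the Fischer rotation procedure: rotate the
  four substituent unit vectors so the first lies on +y and the second in
  the yz plane with negative z, then read the Fischer side of the third
  from the sign of its x coordinate. Before rotating, the four vectors are
  re-centered on their centroid and re-normalized. This is a positive
  radial rescaling with the origin interior to the convex hull, so it
  cannot change the handedness of the configuration, and it makes the read
  well-conditioned even for the flat-plus-one-wedge geometry produced by
  lifting a 2D drawing (where three substituents are coplanar and the raw
  procedure would read an x coordinate near zero). With centering, the
  procedure provably agrees with the sign of
  `det(v2-v1, v3-v1, v4-v1)` up to one fixed global sign, and the test
  suite checks that agreement on 1000 unrestricted random tetrahedra
  against the determinant computed independently.
* The **dummy direction** for a lone-pair center is the antipode of the
  normalized substituent-vector sum — the simplest realization of "the
  point of maximum distance from the three real substituents on the unit
  sphere". For pyramidal arrangements the antipode essentially coincides
  with the true spherical max-min point; for strongly skewed triples the
  maximizer shifts, but both stay on the open side of the substituent
  plane, so the parity is identical either way (both facts are tested
  against a dense grid search).
* **Double-bond sides** compare the components of the two substituent
  vectors perpendicular to the bond axis; a positive dot product means
  same side. A missing substituent's direction is the negative of its
  partner's.

2D drawings are handled by `wedge_lift()`: the far atom of each wedge is
raised (up) or lowered (down) by 0.8 bond lengths, conflicting wedges are
an error, and a topologically stereogenic atom that received no wedge is
skipped — its configuration is simply not stated by the drawing. Wedges on
non-stereogenic atoms are decorative and ignored, so such structures
encode as achiral rather than erroring.

The global sign convention is pinned by one reference molecule:
D-(R)-lactic acid must serialize as `{SA:1,2,3,4,H}`. Its conformer is
hard-coded in the fixture registry with the chiral carbon's substituents
on the four ideal tetrahedral directions.

## Tunable constants

| option | meaning | default |
|---|---|---|
| `mcdl.wedge_z` | wedge lifting height, fraction of bond length | 0.8 |
| `mcdl.coplanar_tol` | minimum affine determinant of four substituent vectors | 1e-3 |
| `mcdl.perp_tol` | minimum perpendicular sp2 component, fraction of bond length | 0.1 |

The two tolerances implement the documented failure modes of poor
drawings: four coplanar substituent vectors and near-linear sp2 angles
both raise ambiguous-geometry errors naming the offending atom or bond,
rather than guessing a configuration.

## Parsing and bond-order reconstruction

`parse_mcdl()` implements the grammar
`composition ("[" connectivity "]")? ("{SA:...}")? ("{SB:...}")?`, with
labels tokenized greedily into element symbols and empty token positions
read as dummies. Validation enforces rank ranges, `x1 < x2`, the
top/bottom and `n1`/`n4` priority invariants, token uniqueness, and that
terminal tokens name actual terminals of the referenced fragment.
Unrecognized trailing `{XX:...}` blocks are kept verbatim with a warning.

MCDL does not store bond orders, so `reconstruct_bond_orders()` assigns
them by backtracking: every atom's bond-order sum must equal a standard
valence (H 1, B 3, C 4, N 3, O 2, F 1, Si 4, P 3/5, S 2/4/6, Cl 1, Br 1,
I 1), with `{SB:}`-marked bonds fixed at order 2. Bonds are processed in a
deterministic order (by fragment ranks, then terminal symbol) and order
values are tried ascending, so the first solution found is the
lexicographically minimal one. When several assignments exist — the
valence-tautomer situation of cyclooctatetraene- or porphyrin-like rings,
which genuinely needs bond-order information the base notation does not
carry — the minimal assignment is returned with a warning.

Round-tripping re-derives abstract configurations from the descriptor
itself: the permutation from the `(top,bottom,left,right)` arrangement to
the internal substituent order, taken modulo even swaps, recovers the
parity without any 3D embedding; an `{SB:}` entry directly states a
same-side relation. Re-encoding through the full canonical pipeline then
maps canonical strings to themselves and valid non-canonical strings to
their canonical representative.

## What the generators emulate

The fixture registry builds each reference molecule programmatically with
ideal local geometry (tetrahedral 109.47 degrees, trigonal 120 degrees,
bond length 1.5): exact local stereochemistry is all perception needs, so
global steric clashes are permitted and irrelevant. Enantiomer pairs whose
absolute configuration is depiction-dependent (the 2-hydroxy-2-
methylbutanoic acid and sulfoxide pairs) are registered as mirror-image
pairs with their descriptor pair asserted as a set; molecules whose
configuration is fixed by the descriptor semantics themselves (the
double-bond examples, D-lactic acid, the S-CHBrClF reference) are pinned
individually.

`random_stereo_molecule()` draws connected acyclic molecules with 4–12
heavy atoms from {C, N, O, S, F, Cl, Br} (carbon-weighted, one-valent
halogens as leaves), upgrades up to two bonds to double bonds where
valences allow, fills hydrogens, and embeds with randomized
configurations at every stereogenic unit. It is deterministic per seed
and restores the caller's RNG state. The generator deliberately emulates
the regime the notation targets — small organic molecules with atomic and
double-bond stereogenic units. It does not produce rings (so ring
perception is exercised only by the cyclohexene-style fixtures), charged
or isotopic species (rejected by design), or the distorted geometries of
hand-drawn structure files; passing the property suites therefore
demonstrates correctness of the combinatorial machinery, not robustness
to low-quality real-world drawings, which surface instead through the
ambiguity errors described above.

Problem sizes used by the shipped checks: the property suites run 1000
random tetrahedra for the parity oracle and 500 random molecules each for
canonical invariance (atom permutation plus rigid motion) and
encode–parse–re-encode identity; these sizes make the sampling error
negligible for yes/no invariants while keeping a full run comfortably
interactive.

## Design choices where the design was open

* **Canonical connectivity rule.** The minimal-serialization rule with
  "exhausted list first" reproduces every connectivity module in the
  reference fixture registry; the notation's original numbering rule is
  not restated here, so the rule is validated against those reference
  descriptors and documented as this package's definition.
* **Search strategy.** The numbering search is a backtracking assignment
  within equal-label classes with sound prefix pruning against the
  incumbent (known neighbor ranks form a prefix of each list; unassigned
  neighbors can only contribute ranks beyond the current block). A hard
  cap of 1e6 visited states raises an explicit capacity error — never a
  silently truncated search. The test suite cross-checks the search
  against a plain full enumeration on all fixtures and a sample of random
  molecules.
* **Scheme multiplicity.** A symmetric constitution can reach the minimal
  connectivity under several numberings even when the stereo outcome is
  forced (trans,trans-hexa-2,4-diene); all minimizers are kept and the
  stereo comparison resolves the rest. This subsumes the "single scheme"
  phrasing for the symmetric trans,trans case: its schemes all emit the
  same stream.
* **Lone-pair centers.** Restricted to three-coordinate sulfur. Trivalent
  nitrogen inverts too quickly at room temperature to be a stereocenter
  in this notation's scope and is excluded.
* **Charges, isotopes, radicals.** Rejected with clear errors; the
  supported element table is H, B, C, N, O, F, Si, P, S, Cl, Br, I.
  Deuterium/tritium are not distinguished from protium: the notation's
  terminal alphabet is element symbols.
* **Single-atom inputs.** MOLFILEs without a bond block are accepted (a
  single atom is a fragment with no terminals) — a deliberate
  generalization over older implementations that refused them.
* **Two-atom molecules.** Both atoms have degree 1; the ASCII-smaller
  element becomes the core, deterministically.
* **Serialization order.** `{SA:}` precedes `{SB:}` when both are
  present; the reference descriptors never combine them, so the order is
  fixed here for determinism.

## Known limitations

Ring double-bond stereochemistry is ignored; allene/axial chirality,
atropisomers and higher-order stereogenic units are out of scope, as are
aromatic perception and any 2D layout generation (decoded molecules are
written with zero coordinates, with the canonical descriptor in a sidecar
report). The canonical numbering search is exponential in the worst case
and is intended for molecules up to a few tens of fragments; beyond the
capacity cap it fails loudly. Bond-order reconstruction warns rather than
disambiguates for valence-tautomeric ring systems.
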