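# mcdl

Canonical chemical line notation with stereochemistry: an R implementation
of the Modular Chemical Descriptor Language (MCDL).

MCDL represents a molecule as semicolon-separated modules. Two modules fix
the constitution — the **composition module**, an ASCII-sorted list of
structural fragments (one core atom plus its degree-1 terminal neighbors,
e.g. `C;CHH;2CHHH;CO;2OH`), and the **connectivity module**, per-fragment
lists of higher-numbered bonded fragments under the canonical minimal
numbering (`[2,3,5,6;4;;;7]`). Two optional modules fix the
stereochemistry:

* `{SA:center,top,bottom,left,right}` — an atomic center written as a
  Fischer projection (horizontal bonds toward the viewer, vertical away),
  with the highest-priority substituent on top, the second at the bottom,
  and left/right chosen so the depicted configuration is preserved under
  even numbers of swaps;
* `{SB:x1dx2,n1,n2,n3,n4}` — a double bond between fragments `x1 < x2`,
  where `n1` is the higher-priority connection to `x1` and `n2` the
  connection to `x2` on the same side of the bond as `n1`.

Substituent priority is the dummy (electron pair / missing sp2 neighbor,
printed as an empty field) first, then fragments by rank, then terminal
atoms by ASCII symbol. When a symmetric constitution admits several
canonical numberings, all of them are explored and the stereo token
streams are compared position by position — atoms before bonds — to pick
the unique canonical descriptor.

The package is for cheminformatics work that needs a compact, canonical,
human-readable identifier with explicit stereochemistry: registry
deduplication, round-trip validation of structure files, and teaching the
Fischer/priority view of stereo descriptors. It reads and writes MDL
MOLFILE V2000 / SDF (3D coordinates, or 2D drawings with wedge bonds),
perceives stereogenic atoms (including lone-pair sulfur centers) and
acyclic double bonds by full-depth branch hashing, and parses MCDL strings
back into molecular graphs, reconstructing bond orders from standard
valences.

## A worked example

D-(R)-lactic acid, built from the fixture registry and encoded:

```r
library(mcdl)

fx <- reference_fixture("lactic-acid-D")
mcdl_encode(fx$graphs[[1]])
#> [1] "CH;CHHH;CO;2OH[2,3,4;;5]{SA:1,2,3,4,H}"
```

Reading the string: the molecule has five fragments — the chiral `CH`
(rank 1), `CHHH` (2), the carboxyl `CO` (3) and two `OH` (4, 5); fragment
1 is bonded to 2, 3 and 4, fragment 3 to 5. The `{SA:}` entry says the
chiral fragment 1 carries, in Fischer orientation, fragment 2 on top,
fragment 3 at the bottom, fragment 4 (the hydroxyl) on the left and the
terminal hydrogen on the right — the R configuration. In the mirror
image's descriptor, left and right exchange:

```r
mcdl_encode(mirror_graph(fx$graphs[[1]]))
#> [1] "CH;CHHH;CO;2OH[2,3,4;;5]{SA:1,2,3,H,4}"
```

Round-tripping a descriptor through the parser reconstructs the graph
(with bond orders re-derived from valences) and re-encodes it; valid but
non-canonical strings canonicalize:

```r
roundtrip_canonicalize("2CH;2CO;4OH[2,3,5;4,6;7;8]{SA:1,2,3,H,5;2,1,4,6,H}")
#> [1] "2CH;2CO;4OH[2,3,5;4,6;7;8]{SA:1,2,3,5,H;2,1,4,H,6}"
```

Batch workflows mirror the functions: `mcdl_encode_file()` (SDF to MCDL,
one descriptor per line), `mcdl_decode_file()` (MCDL to SDF plus a stereo
report) and `mcdl_roundtrip_file()` (encode, decode, re-encode, compare
byte for byte). A thin command-line wrapper ships in `exec/mcdl`:

```sh
Rscript exec/mcdl encode --in batch.sdf --out batch.mcdl
Rscript exec/mcdl roundtrip --in batch.sdf --report report.tsv
```

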