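Package: mcdl
Title: Modular Chemical Descriptor Language with Stereochemistry
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Encode molecules into canonical Modular Chemical Descriptor
    Language (MCDL) strings and parse them back. Reads MDL MOLFILE V2000 and
    SDF input (3D coordinates, or 2D coordinates with wedge/hash bonds),
    decomposes molecules into structural fragments, derives the canonical
    composition and connectivity modules, perceives stereogenic atoms and
    double bonds, and emits the {SA:} and {SB:} stereochemical modules built
    on Fischer-projection parities and fragment priority ranking. The parser
    reconstructs molecular graphs from MCDL strings, including acyclic
    bond-order assignment from standard valences, and re-canonicalizes
    descriptors for round-trip validation. Includes programmatic builders for
    reference molecules, a seeded random stereo-molecule generator, and batch
    SDF/MCDL conversion utilities with a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
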