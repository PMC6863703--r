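Package: hbnetforge
Title: Enumeration and Scaffold Matching of Hydrogen-Bond-Connected Enzyme Active Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computational enzyme design around hydrogen-bond
    connectivity. Starting from a two-dimensional "wiring diagram" of an
    active site (which side-chain functional groups hydrogen-bond or
    covalently bond to which ligand sites, and to each other), the package
    enumerates all grid-deduplicated 3D placements of the functional groups
    around the ligand, assembles fully connected, clash-free catalytic
    networks, expands them into full side chains (inverse rotamers),
    clusters networks on the coordinates of their central functional
    groups, and places them into protein scaffold backbones with a
    rigid-body transform-hashing matcher, reporting how often the full
    specified connectivity is realized.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
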