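Package: xtalclust
Title: Clustering Protein Interfaces Across Crystal Forms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Enumerates every unique protein-protein interface in a crystal
    lattice from crystallographic structure files, groups entries into
    crystal forms, and clusters homologous interfaces across crystal forms
    using a Jaccard-style similarity score computed on contacts mapped to
    profile-HMM match positions. Also clusters domain-peptide binding modes,
    domain-ligand contact sites, and domain-nucleic-acid interfaces, and
    answers protein-list interaction queries against the resulting cluster
    store. Includes a synthetic-crystal generator so the whole pipeline is
    testable without downloading structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
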