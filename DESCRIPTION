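Package: protacR
Title: Rule-Based Decomposition of PROTAC Degraders into Warhead, Linker
    and E3 Ligase Ligand
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic decomposition of heterobifunctional degraders
    (PROTACs) given as SMILES into their three constituent moieties --
    warhead, linker and E3 ligase ligand -- by bidirectional library
    matching with strict structural conservation filters (heavy-atom and
    ring-count conservation, single continuous linker). Includes fragment
    library curation utilities, a linker physicochemical descriptor suite
    (MW, nC, TPSA, HBD, HBA and the Kier molecular flexibility index) for
    linkerology analysis, a synthetic-PROTAC fixture generator with known
    ground truth, a batch driver and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    methods,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
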