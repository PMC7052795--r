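Package: loopassembly
Title: Simulation and Planning of Recursive Type IIS (Loop/Golden Gate) DNA Assembly
Version: 0.1.0
Authors@R:
    person("Loopassembly", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: In-silico engine for recursive Type IIS digestion-ligation
    ("Golden Gate") cloning in the Loop/uLoop style. Models BsaI- and
    SapI-mediated one-pot reactions on annotated circular and linear DNA,
    enforces the odd/even overhang grammar and part nomenclature, plans and
    simulates hierarchical multi-transcription-unit constructs up to
    receiver-free level-4 concatemers, predicts verification readouts
    (restriction digest profiles, in-silico PCR) and emits bench recipes.
    Includes a deterministic synthetic fixture generator (vector kits, part
    libraries, benchmark assembly trees) so everything runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
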