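Package: pepdegradome
Title: Comparative Analysis of Endogenous Peptidomes and Protein Degradation Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing endogenous (non-digested) peptide pools between
    cellular and secreted compartments and between control and hormone-treated
    conditions. Provides peptide-to-precursor mapping and replicate filtering,
    condition set algebra and fold-change estimation, protein degradation
    pattern (PDP) matrices over relative-position windows, amino-acid and
    terminal-residue composition profiles with background peptide generation,
    AAindex physicochemical property screening with Ward clustering and
    cluster enrichment, membrane-topology localization enrichment, consensus
    antimicrobial-candidate triage from external predictor scores, and a
    seeded in-silico proteolysis simulator with ground truth for closed-loop
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    seqinr,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
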