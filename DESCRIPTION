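Package: tccselect
Title: Selectivity Triage of T-Type Calcium Channel Blocker Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening phenylalkylamine-type blocker candidates for
    selectivity towards T-type (Cav3.x) over L-type (Cav1.x) voltage-gated
    calcium channels. Implements a point-charge Coulomb model of how the
    domain-III lysine adjacent to the selectivity-filter aspartate attenuates
    or reverses the calcium-aspartate attraction in T-type channels, a
    residue-label nomenclature parser and channel-family classifier over
    S5/P-loop/S6 pore-domain alignments, conversion of docking free energies
    to dissociation constants, a domain-based selectivity rule for docking
    tables, drug-likeness descriptor computation and reference-based
    filtering (logP, synthetic accessibility, QED), and a synthetic cohort
    generator with known ground truth for validating the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, Biostrings, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
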