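Package: lancmine
Title: Genome Mining for Lanthipeptide Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R: person("Lancmine", "Developers", email = "lancmine@example.org",
    role = c("aut", "cre"))
Description: Detects LanC-anchored lanthipeptide biosynthetic gene clusters
    in annotated prokaryotic genomes, assigns them to lanthipeptide classes
    I-IV from profile-HMM evidence, enumerates candidate precursor open
    reading frames, splits precursor peptides into leader and core regions
    with a cleavage-motif heuristic, and scores candidates with an
    ANOVA-selected support vector machine combined with a configurable
    heuristic rubric. Ships a deterministic synthetic-genome generator so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: HMMER3 (hmmbuild, hmmsearch on PATH)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
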