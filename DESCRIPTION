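Package: viroscreen
Title: Homology-Based Virome Characterization from RNA-Seq Assemblies
Version: 0.1.0
Authors@R:
    person("viroscreen", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A multi-step, homology-based pipeline for characterizing the
    viral community (virome) hidden in host RNA-seq data. Starting from de
    novo assembled contigs and tabular homology-search results, the package
    performs host read subtraction, three-way contig triage with homology
    trimming, an all-proteins screen, eukaryotic-virus confirmation via
    taxonomy lineage climbing, family-level annotation, remapping-based
    abundance quantification (TPM/1000, depth-normalized RPM, z-scores),
    core-virome presence/absence intersection analysis, and inter-population
    factor analysis with per-factor Welch tests. A synthetic-community
    generator with a known ground-truth manifest makes every stage testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
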