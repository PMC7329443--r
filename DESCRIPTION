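Package: hydrovent
Title: Comparative Metagenomics of Active and Inactive Hydrothermal Vent Chimneys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the microbial communities of deep-sea
    hydrothermal sulfide chimneys from shotgun metagenomes: length-normalized
    per-million gene abundance and gene-level taxonomic attribution;
    two-sample differential gene tests (two-sided Fisher's exact test with
    Newcombe-Wilson confidence intervals and Benjamini-Hochberg FDR);
    refinement, dereplication and quantification of metagenome-assembled
    genomes (MAGs); coverage-trend index-of-replication (iRep) estimation;
    a declarative rule engine for metabolic pathway completeness calling;
    and zero-magnesium endmember extrapolation of vent-fluid chemistry.
    A seeded synthetic-community generator produces every input the pipeline
    consumes so all stages are testable without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
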