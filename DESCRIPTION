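Package: islandmeth
Title: Whole-Genome Bisulfite Methylome Analysis with CpG-Island
    Sequence Embedding
Version: 0.1.0
Authors@R:
    person("Methylome", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing whole-genome bisulfite sequencing (WGBS)
    methylomes of outbred mammalian cohorts: CpG-site quality filtering and
    beta-value computation, de novo CpG-island detection under
    composition criteria (Gardiner-Garden-Frommer and Takai-Jones style),
    differentially methylated region and methylation-variability region
    calling, genomic-feature and repeat-subfamily enrichment statistics,
    and a native byte-pair-encoding tokenizer plus masked-language-model
    transformer encoder for embedding CpG-island sequences. Includes a
    fully seeded synthetic-data generator (genome, annotations,
    beta-binomial methylation counts with planted effects) so the whole
    pipeline is testable without external downloads, and a
    configuration-driven command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
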