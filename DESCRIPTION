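Package: stoolomics
Title: Integrated Faecal Small ncRNA and Microbiome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for profiling host small non-coding RNAs
    (miRNAs and piRNAs) and microbial communities from stool samples. Includes
    seed-constrained read mapping to an ncRNA reference with
    expectation-maximization resolution of multimapping reads, a greedy
    sequence-clustering step whose per-sample cluster cardinalities drive TMM
    scaling factors, per-sample differential expression by Fisher's exact test
    with pseudocount fold changes and Benjamini-Hochberg correction,
    cross-sample target-gene intersection with gene-set annotation, and
    OTU-table summaries (relative abundance, alpha diversity, taxon ratios,
    group prevalence partitions). A synthetic-data module generates every
    input the pipeline consumes so all stages are testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
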