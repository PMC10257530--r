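Package: methylsynergy
Title: RRBS Differential Methylation, DMR Tiling, Feature Enrichment and
    Bliss Drug-Synergy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for downstream analysis of reduced
    representation bisulfite sequencing (RRBS) methylomes from multi-group
    drug-treatment designs, together with Bliss-independence scoring of
    drug-combination viability plates. Reads per-cytosine bisulfite call
    files (Bismark cytosine-report and coverage dialects), merges CpG
    strands, unites replicates into coverage-filtered group matrices, calls
    differentially methylated cytosines with a binomial logistic
    likelihood-ratio test and Benjamini-Hochberg correction, tiles them
    into differentially methylated regions with gap-based chaining and
    symmetric extension, and characterises the regions by CpG-level
    odds-ratio enrichment against genomic feature tracks, TSS-distance
    bins, feature-centered methylation profiles and basal-plus-extension
    gene association. A synthetic bisulfite cohort generator with planted
    differentially methylated regions, bimodal baseline methylomes and
    negative-binomial coverage provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
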