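Package: b1profiler
Title: Thiamine (Vitamin B1) Pathway Genotyping and Depth-Profile Analysis
    for Marine Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring vitamin B1 (thiamine) physiology of marine
    bacteria and archaea from genome annotations and for relating it to
    depth-resolved community and metabolite data. Parses homology-search hit
    tables, applies tiered e-value filters, and builds per-genome gene
    presence matrices; classifies genomes and metagenome-assembled genomes
    (MAGs) into B1 prototroph/auxotroph genotypes with an
    incompleteness-aware confidence model; normalizes ORF-level read counts
    to RPKM and aggregates gene and transcript depth profiles; summarizes
    amplicon communities (relative abundance, Shannon diversity, Bray-Curtis
    dissimilarity with UPGMA clustering, rank tests, indicator species
    analysis); and computes replicate statistics, oxygen-minimum-zone layer
    flags, fold changes, and local maxima for dissolved thiamine-related
    compound depth profiles. A synthetic-data module generates every input
    with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
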