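Package: mutprofiler
Title: Somatic Mutation Density Profiles and Regulatory-Region Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for asking where somatic mutations concentrate in a genome.
    Builds scaled metagene mutation-density profiles around gene and miRNA
    bodies and peak-centered profiles around CTCF, histone-mark and DNase
    peaks; tests enrichment against flanking-region and matched random-region
    nulls with Mann-Whitney rank tests and Benjamini-Hochberg correction;
    relates mutation occurrence to CpG observed/expected ratio, CpG and GC
    content in sliding windows, and to CpG methylation levels around mutated
    sites; and ships a fully specified synthetic-data generator (toy genome,
    annotation, peak sets, methylation landscape, mutation cohort with planted
    fold-enrichments, a methylation-dependent C-to-T rate multiplier and
    hypermutator samples) so every analysis can be exercised end-to-end
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
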