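Package: seriolapop
Title: Population Genomics of Pacific Yellowtail Kingfish Marker Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the population-genetic analyses used to resolve the
    structure of Pacific yellowtail kingfish (Seriola lalandi): collapsing
    aligned mtDNA COI sequences to haplotypes and variable-site tables,
    fixed-difference diagnostic-site discovery, sequence and microsatellite
    diversity estimators (haplotype diversity, nucleotide diversity, observed
    and unbiased expected heterozygosity, F_IS), hierarchical AMOVA with
    Phi-statistics and permutation tests, pairwise F_ST, SNP/DArT marker
    quality control and population-unique marker discovery, a SNP-tag
    sequence-homology (dissimilarity) statistic for fixed-length genotyping
    tags, molecular-clock divergence dating, and seedable synthetic-data
    generators (region-structured haplotype spectra, island-model
    microsatellites, Balding-Nichols SNP/dominant marker matrices) with
    recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
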