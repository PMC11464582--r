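Package: popgenpipe
Title: Genome-Wide SNP Diversity, Inbreeding, Linkage Disequilibrium and
    Population Structure Analysis for Small Livestock Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete SNP-array population-genomics workflow for small,
    labelled diploid populations such as local livestock conservation
    nuclei. Reads, writes and merges PED/MAP genotype data; performs
    call-rate, minor-allele-frequency and windowed linkage-disequilibrium
    (LD) pruning quality control; computes per-population diversity
    statistics (MAF spectra, observed/expected homozygosity, F_IS, F_HOM)
    and per-marker Weir-Cockerham F_ST; estimates LD decay and LD-based
    effective population size per past generation; detects runs of
    homozygosity (ROH) with a sliding-window caller and derives F_ROH by
    length class; summarises population structure through PCA, IBS nearest
    neighbours, pairwise F_ST with Slatkin linearization and migrant
    numbers, Nei distances with neighbour-joining trees, and k-nearest-
    neighbour networks; fits a maximum-likelihood admixture model with
    cross-validation over k; runs a PCA-based outlier scan with genomic-
    inflation control and Benjamini-Hochberg correction; and ships a
    synthetic-genotype generator (Balding-Nichols, forward Wright-Fisher,
    ROH implants, admixture mixtures) providing ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
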