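Package: strepclades
Title: Streptococcus Clade Profiling of Oral Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Clade-level profiling of oral Streptococcus communities from
    shotgun-metagenomic taxonomic tables. Assigns species to phylogenetic
    clades by average-nucleotide-identity clustering with dendrogram-based
    label propagation, computes layered relative-abundance profiles and
    per-sample clade dominance, provides compositionally-aware statistics
    (centered log-ratio transform, CLR-Pearson and proportionality
    correlation, permutation FDR cutoffs, CLR-PCA, canonical-correlation
    metadata screening), prevalence-filtered Wilcoxon enrichment testing
    with rank-based effect sizes, cumulative-percent-decay preservation QC
    for ancient samples, and a calibrated synthetic-cohort generator for
    end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
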