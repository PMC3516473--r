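Package: hewscan
Title: Selective-Sweep Scans of Phased Haplotype Fragments with the
    Compound HEW Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Population-genetic analysis of short, phased haplotype
    alignments such as amplicon-resequenced gene fragments from
    structured mosquito populations.  Computes silent-site summary
    statistics (Watterson's theta, nucleotide diversity, Tajima's D,
    normalized Fay and Wu's H, Ewens-Watterson haplotype homozygosity),
    tests them against neutral coalescent null distributions with a
    jointly calibrated compound HEW decision rule, measures
    differentiation between population strata with Weir-Cockerham F_ST
    and permutation tests, fits a multilocus HKA model of polymorphism
    and divergence, and dissects putative sweeps through linkage
    disequilibrium, haplogroup delineation, clade-conditioned coalescent
    simulation, neighbor-joining trees and sliding-window Jukes-Cantor
    divergence.  A synthetic-data generator produces complete study
    bundles under neutral, growth, bottleneck and sweep scenarios so the
    whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
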