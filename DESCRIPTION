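Package: omegascan
Title: Linkage-Disequilibrium-Based Selective Sweep Detection with the Omega Statistic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects selective sweeps in intra-species polymorphism data from
    the characteristic linkage-disequilibrium pattern they leave: elevated
    squared allelic correlation (r2) within each flank of a swept site and
    depressed correlation across it, summarised by the omega statistic.
    Implements the dynamic-programming cumulative LD-sum matrix and
    grid/window scan semantics, a tiled work-partitioning planner with
    memory budgeting and balanced omega queues, a suite of classical
    neutrality statistics (Tajima's D, Fu and Li's D* and F*, normalized
    Fay and Wu's H, Depaulis-Veuille K and H, Hudson's C) for comparison,
    readers for FASTA, Hudson's ms format and a VCF subset, a rescaled
    Wright-Fisher simulator with bottleneck demographies and
    trajectory-conditioned sweeps, and a sensitivity/specificity
    evaluation harness with percentile thresholds from per-replicate
    extrema.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    vcfR,
    parallel,
    jsonlite,
    withr
Config/testthat/edition: 3
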