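Package: ucrsim
Title: Self-Correction Artifacts and Uncovered Regions in Allopolyploid
    Long-Read Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates allotetraploid genomes, noisy long reads and accurate
    short reads, and reproduces the mechanism by which consensus-based
    self-correction of high-error long reads introduces artificial errors at
    subgenome-divergent sites.  Provides truth-tracked read simulation with
    per-base error ledgers, overlap clustering and majority-vote correction
    with removed/retained/introduced error accounting, coordinate-preserving
    consensus assembly and polishing, a seed-and-extend short-read mapper,
    and the assembly-evaluation statistics built on them: depth profiles,
    coverage at depth thresholds, zero-coverage (UCR) intervals, per-bin
    mismatch and gap rates, pileup-based heterozygous-site and
    complete-discordance calling, and the divergence-versus-UCR correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    GenomicAlignments
LinkingTo: Rcpp
Config/testthat/edition: 3
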