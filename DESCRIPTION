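Package: dsfdr
Title: Discrete False Discovery Rate Control for Sparse Microbiome Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Permutation-based discrete false-discovery-rate (DS-FDR) control
    for differential-abundance testing on sparse feature-by-sample count
    tables, together with the Benjamini-Hochberg (BH) and filtered-BH (FBH)
    comparators. Test statistics are rank based (mean-rank difference or
    Mann-Whitney U) and the null distribution is obtained by joint label
    permutation, which preserves both the discreteness of the statistics and
    the dependence across features. Includes multinomial community simulators
    with differential, null and rare taxon blocks, data-driven resample-split
    and signal-spiking protocols, and a replicate-based evaluation harness for
    FDR and power, plus abundance-filtering and subsample power-curve sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), biomformat, optparse, withr
Config/testthat/edition: 3
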