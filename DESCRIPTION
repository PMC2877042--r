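Package: xsmm
Title: Positional and Type Effects of Single-Base Probe-Target Mismatches
    on Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Discovers perfect-match/mismatch (PM/MM) probe pairs across two
    25-mer oligonucleotide array designs that share consensus transcript
    sequences, estimates the per-pair log2(PM/MM) signal loss from
    probe-level intensities under a balanced tissue-by-chip design, and
    summarises mismatch effects by probe position (1-25) and by the 12
    ordered mismatch types.  Includes within-replicate-group quantile
    normalization, a semi-global probe-to-consensus aligner with a
    sliding-window fast path, positional spread regression (MAD on median),
    position-group contrasts with pooled t-tests, identical-probe controls,
    and cross-study comparison of mismatch-type stability orders
    (notation conversion, rank vectors, Spearman/Pearson correlation,
    Watson-Crick outlier flagging).  A synthetic data generator with known
    positional and type penalties allows the full pipeline to be exercised
    end to end against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
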