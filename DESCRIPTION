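Package: standr
Title: Design of Ultra-Stable Cytoplasmic Antibodies by Charge Engineering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for engineering ultra-stable cytoplasmic antibodies
    (STANDs) by epitope-tag fusion. Computes peptide net charge across pH
    with a Henderson-Hasselbalch isolated-residue model, solves isoelectric
    points by bisection, assembles scFv/tag fusion constructs, screens them
    against low-pI / strong-negative-charge-at-pH-6.6 design criteria, and
    supplies the supporting analyses: aggregation-rate summaries from cell
    counts, Pearson correlation of charge versus aggregation with t-based
    and permutation p-values, Hill-Langmuir saturation-binding fits (Kd,
    Bmax), thermal-unfolding half-life fits, and seeded synthetic-data
    generators for end-to-end self-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    minpack.lm,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
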