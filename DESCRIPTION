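Package: epinipt
Title: Epigenetic Non-Invasive Prenatal Testing from Targeted CG Coverage Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for epigenetic non-invasive
    prenatal testing (NIPT) from cell-free DNA profiles of unmodified (uCG)
    and 5-hydroxymethylated (5hmCG) CG dinucleotides. Provides a synthetic
    maternal/fetal cfDNA count generator emulating targeted CG sequencing,
    per-CG read assignment and chromosome/window coverage statistics,
    ordination-based sample quality control, reference-chromosome-normalized
    Z-score trisomy-21 calling with cross-validated classification and
    read-depth titration, windowed differentially modified region (DMR)
    discovery by logistic likelihood-ratio testing with FDR control,
    annotation enrichment analysis, and a bin-count regression estimator of
    fetal fraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
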