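Package: riboframe
Title: Ribosome Rotation States, 16S rRNA Base Intercalation into mRNA, and
    -1 Frameshift Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for surveying bacterial ribosome structures for the
    geometric relationship between 16S rRNA base A1503 (and optionally
    C1397) and messenger RNA bases: reading mmCIF/PDB coordinate files,
    identifying rRNA/mRNA/tRNA chains, establishing the mRNA position
    register anchored at the P-site codon, classifying the query base as
    intercalated, stacked or retracted from base-centroid and base-plane
    geometry, measuring 30S body and head rotation angles against a
    classical-state reference by least-squares superposition and axis-angle
    (Euler-Rodrigues) decomposition, and aggregating per-structure calls
    into state-by-contact summary tables and rotation scatter exports.
    Includes seeded generators of labelled synthetic base-stack scenes and
    two-domain subunits for end-to-end validation without downloads, and a
    companion module implementing methionine-normalized quantification of
    -1 programmed frameshifting assays (percent frameshift, -1/0-frame
    ratio, relative translation activity, replicate summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
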