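Package: afmwlc
Title: Worm-Like-Chain Analysis of DNA Contours in AFM Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the mechanics and topology of DNA and
    protein-DNA complexes imaged by atomic force microscopy (AFM). The
    package simulates two-dimensionally equilibrated worm-like chains and
    renders them as AFM-like height maps, segments and traces molecular
    backbones at subpixel accuracy, estimates persistence length from
    tangent-tangent correlation decay, computes bending-angle and
    contour-length statistics, classifies molecule topology (linear, open
    circle, plectoneme, compact), measures superhelical axis lengths, and
    provides twist-writhe-linking-number bookkeeping for protein-induced
    duplex unwinding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    minpack.lm,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
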