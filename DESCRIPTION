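Package: nsun6kit
Title: Substrate Recognition and Biophysics of Archaeal and Human NSun6
    tRNA m5C72 Methyltransferases
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing substrate recognition by NSun6-family
    tRNA:m5C72 methyltransferases. Parses tRNA sequences into annotated
    cloverleaf structures with canonical numbering, extracts the acceptor-stem
    identity elements that govern recognition (the CCA terminus, target site
    C72, discriminator base N73 and base pair 2:71), classifies tRNAs under
    archaeal (PhNSun6) or eukaryotic (hNSun6) rule sets, and generates
    constraint-satisfying synthetic tRNA scaffolds. Also simulates and fits
    steady-state methyl-transfer kinetics by double-reciprocal
    (Lineweaver-Burk) regression and two-state UV melting curves with
    first-derivative melting-temperature estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
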