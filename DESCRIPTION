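Package: lymphovac
Title: Quantifying Lymphocyte Vacuolization as a Lysosomal Storage
    Disease Severity Measure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify lymphocyte vacuolization as a severity
    measure for CLN3 disease (juvenile neuronal ceroid lipofuscinosis)
    and related lysosomal storage disorders. Implements manual blood
    smear scoring along two axes (percentage of vacuolated lymphocytes
    and vacuoles per affected cell), flow-cytometry lymphocyte subset
    gating with an NK-cell internal positive control for LAMP-1 and
    perforin, imaging-flow-cytometry style per-cell LAMP-1
    quantification (Otsu whole-cell masks from the CD4 channel and
    sliding-threshold intensity distribution curves), genotype to
    phenotype-class mapping, and a longitudinal linear mixed model of
    severity with per-patient random effects. A synthetic-data
    generator emulates the cohort, flow samples, and single-cell image
    pairs with known ground truth so that every stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    nlme,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
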