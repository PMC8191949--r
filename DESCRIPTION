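Package: phageNucProfiler
Title: Quantifying Protein Localization Relative to the Jumbo-Phage
    Nucleus in Rod-Shaped Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying where fluorescently tagged proteins sit
    relative to the phage nucleus of jumbo-phage-infected rod-shaped
    bacteria. Provides length- and end-normalized axial fluorescence
    intensity profiles, per-cell localization phenotype calls
    (nucleus-imported, nucleus-excluded, or mixed/ambiguous), Otsu-mask
    quantification of DAPI-stained phage nucleoids with
    complementary-mask background estimation, and group comparisons of
    nucleoid intensity. A seeded synthetic micrograph generator renders
    spherocylindrical cells with a central nucleus disk, Gaussian PSF
    blur, and Poisson + Gaussian camera noise, with pixel-level ground
    truth, so the whole pipeline is testable without real micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
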