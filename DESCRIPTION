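Package: biofilmscape
Title: Morphometrics of Phototrophic Biofilm Landscapes Along Hydraulic Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of biofilm surface topography from optical
    coherence tomography (OCT) digital elevation models (DEMs): moving-window
    landscape morphometrics (biovolume, coverage, porosity, Haralick textural
    correlation), segmentation of the landscape into base biofilm, protruding
    clusters and troughs by deviation from the local average thickness,
    temporal differencing of DEM series to quantify growth and biomass
    displacement, segmented (breakpoint) regression of landscape metrics
    against bed shear stress with bootstrap significance testing, and
    statistics for oxygen microprofiles (local gradients, light:dark flux
    ratios, Brown-Forsythe and Welch tests). Includes a ground-truthed
    synthetic landscape and oxygen-profile generator emulating slow-flow
    (cluster-and-trough) and fast-flow (coalescent carpet) morphotypes for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
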