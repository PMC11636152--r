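Package: fencorr
Title: Correlative Morphometry of Liver Sinusoidal Endothelial Cell Fenestrations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for correlative multimodal imaging of
    fenestrations, the 50-350 nm transcellular nanopores of liver sinusoidal
    endothelial cells (LSEC). Generates ground-truth sieve-plate geometries and
    renders them as SEM-like, optical (SIM/STED-like) and AFM Quantitative
    Imaging force-curve data; segments fenestrations by threshold-based
    morphometry (area, equivalent diameter, ellipse axes, roundness); processes
    per-pixel force-distance curves (contact-point detection, topography
    reconstruction at a chosen load force, Hertz elasticity fitting, force
    tomography); registers two modalities from landmarks and matches pores
    one-to-one by optimal assignment; and computes distributional statistics
    (Gaussian peak fits, paired regressions, dehydration dilation percentages,
    wet/dry correction coefficients, porosity and frequency).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    clue,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vegan,
    withr
Config/testthat/edition: 3
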