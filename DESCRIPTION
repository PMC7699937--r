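Package: drtb
Title: Stomatal Segmentation by Delaunay-Rayleigh Threshold Binarization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic segmentation of stomata in leaf-epidermis micrographs
    using the spatial statistics of stomatal patterning. A preprocessing chain
    (Perona-Malik anisotropic diffusion, mean-shift intensity quantization and
    Hadamard division of the saturation channel by the clustered red channel)
    produces a grey-scale image that is binarized at every candidate threshold;
    for each threshold, region centroids are Delaunay-tessellated and the
    empirical distribution of tessellation edge lengths is compared to a
    Rayleigh distribution by root-mean-square deviation. The threshold whose
    edge-length frequencies are closest to the Rayleigh law gives the final
    segmentation. Includes the center-distance precision/recall evaluation
    protocol and a seeded synthetic generator of stomata-like images with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    deldir,
    png,
    tiff,
    jpeg,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
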