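Package: rootarch
Title: Root System Architecture Trait Extraction from Seedling Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Phenotyping engine for 2D images of seedling root systems
    grown on blue germination paper. Segments roots from the blue
    background (heuristic HSV thresholding, k-means colour clustering,
    or a small convolutional auto-encoder), reduces the mask to a
    one-pixel skeleton graph, automatically identifies the primary
    root, and extracts a catalogue of root-system-architecture traits:
    lengths, counts, areas, angles (windowed Fourier + Hough), shape
    profiles (elliptical Fourier descriptors), and ratios. Includes the
    downstream quantitative-genetics stage (IQR outlier filtering,
    REML variance components and BLUPs, entry-mean heritability, Tukey
    HSD groupings, genetic coefficient of variation, trait
    correlations, Kolmogorov-Smirnov directionality tests) and a
    synthetic root-image generator with analytic ground truth so every
    stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    lme4,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jpeg,
    optparse,
    withr,
    multcomp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
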