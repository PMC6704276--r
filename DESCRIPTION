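Package: msi2lmd
Title: Co-Registration of Mass Spectrometry Imaging, Histology, and Laser
    Microdissection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to transfer spatial regions of interest from mass
    spectrometry imaging (MSI) to a laser microdissection (LMD) system via
    an intermediate optical and H&E histology image. Provides landmark-based
    affine co-registration between named coordinate frames with
    registration-error estimation and additive/quadrature propagation,
    TIC normalization and tumor masking of MSI data, spatial segmentation by
    non-negative matrix factorization with silhouette-based selection of the
    number of segments, MATLAB-compatible morphological post-processing of
    the segmentation image (opening, small-area removal, hole filling,
    nearest-neighbour warping, Moore-neighbour boundary tracing), export of
    the resulting shapes to Leica LMD-compatible XML, and downstream
    label-free microproteomics statistics (flag filtering, log2 z-scoring,
    exclusive regulation calls, complete-linkage clustering with k-means
    preprocessing). A phantom generator produces synthetic MSI, image, and
    protein data with known ground truth for testing the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    xml2,
    jsonlite,
    ape,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
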