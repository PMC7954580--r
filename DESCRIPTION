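Package: glottikym
Title: Hybrid K-Means/Active-Contour Detection of Vocal Fold Edges in
    High-Speed Videoendoscopy Kymograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects the left and right vocal fold edges in kymograms
    extracted from color high-speed videoendoscopy (HSV) recordings of
    connected speech. Each kymogram is preprocessed (moving-average
    smoothing, Tukey weighting about the glottal midline), described by
    per-pixel red/green intensity and gradient-magnitude features, and
    partitioned in chunks of at most 50 frames by two-class k-means with
    k-means++ seeding. The glottal cluster is identified from the first
    moment of inertia of the inverted green channel, grown into a glottal
    mask by seeded 8-connected region growing, and the resulting edge
    traces initialize an open active contour (snake) that refines the
    edges against the image gradient. Detected edges are registered back
    to video-frame coordinates. A synthetic kymogram and frame-stack
    generator with exact ground-truth edges supports end-to-end
    validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    png,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'avi.R'
    'utils.R'
    'cluster.R'
    'synthgen.R'
    'snake.R'
    'glottis.R'
    'features.R'
    'videoio.R'
    'kymograph.R'
    'pipeline.R'
    'evalsuite.R'
    'glottikym-package.R'
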