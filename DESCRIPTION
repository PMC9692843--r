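Package: testaclust
Title: Unsupervised Clustering of Seed-Coat Surface Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for grouping seed-coat (testa) surface
    texture images by unsupervised learning. Generates labeled synthetic
    testa patches with controllable anticlinal wall undulation and
    periclinal sculpture, derives grayscale, binary-threshold and
    colored-component representations, selects cluster counts by the elbow
    and silhouette criteria over k = 2..10, runs a five-method clustering
    battery (k-means, k-means++, minibatch k-means, spectral, Birch), and
    computes cross-run overlap relations, threads and a six-level
    per-image agreement grouping (SI/SS/SM/NS/PS/PD).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    cluster,
    igraph,
    EBImage,
    withr,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    mclust,
    kernlab
Config/testthat/edition: 3
RoxygenNote: 7.3.3
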