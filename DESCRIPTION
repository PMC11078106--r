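Package: hotspotter
Title: Spatial Statistics of Synaptic Input to Retinal Ganglion Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing the spatial organisation of synaptic input
    to skeletonized neuron reconstructions from volume electron microscopy.
    Provides readers and writers for annotation-disk skeletons and synapse
    tables, a synthetic reconstruction generator with planted synapse
    clusters, convex-hull dendritic-field morphometry and inner plexiform
    layer depth profiles, mass-conserving smoothed 2D density maps,
    Gaussian-mixture hotspot detection with Calinski-Harabasz model
    selection and Mahalanobis outlier exclusion, and connectivity
    statistics (geometric run-length null, per-partner synapse profiles,
    Fisher's exact comparisons, dendritic-field overlap analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
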