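Package: flatmorph
Title: Geometric Morphometric Identification of Flatfish Vertebrae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Landmark-based geometric morphometric toolkit for identifying
    flatfish (Pleuronectiformes) vertebrae from two 2D views (anterior and
    sinistral). Provides TPS landmark file input/output, generalized
    Procrustes superimposition, thin-plate-spline estimation of missing
    landmarks, interquartile-range outlier screening, per-view and
    combined-view principal component analysis of shape, a two-stage
    PCA-to-LDA classifier with bootstrap accuracy evaluation and hierarchical
    (vertebra type, family, species) decision chaining, a fragment-aware
    identification protocol for degraded archaeological samples, and a
    synthetic two-view landmark data generator emulating taxon structure,
    digitisation nuisance, mirror (left-/right-eyed) forms and taphonomic
    landmark loss.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), MASS, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
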