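Package: undulaR
Title: Posture, Calcium-Imaging and Correlation Analysis of C. elegans Undulatory Locomotion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for behavioral video and calcium imaging of
    single crawling Caenorhabditis elegans: Otsu-based worm segmentation and
    100-point midline skeletonization, bending-angle kymographs and 3-point
    posture angles, eigenworm decomposition, track quality-control filters,
    ROI fluorescence trace extraction with dF/F and ratiometric dR/R
    normalization, dual-neuron spot tracking with vulva-angle geometry, and
    event-wise cross-correlation of neural activity with body bending. A
    synthetic-data module generates worm videos and fluorescence movies with
    known ground truth so that every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    utils,
    EBImage,
    igraph,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
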