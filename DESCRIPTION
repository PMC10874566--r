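Package: clamap
Title: Claustrum Demarcation from Marker Labelling and Retrograde Tracing Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative image analysis for demarcating the mouse claustrum
    from combined claustrum-enriched (Nurr1, Nr2f2) and claustrum-devoid (Tle4)
    marker labelling plus retrograde tracing. Provides a synthetic multi-channel
    confocal slice simulator with known ground truth, maximum-intensity
    projection and TIFF stack I/O, automated cell detection, cross-channel
    colocalization (Venn) quantification, kernel-density zone delineation with
    vertex-centroid registration across animals, dual-axis z-scored intensity
    profiling realigned to the retrograde peak, and the associated group
    statistics (pooled t-tests, one-way ANOVA with Bonferroni post hoc).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
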