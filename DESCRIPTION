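Package: catvoc
Title: Acoustic Characterization of Cat Meows and Human-Listener Survey Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing domestic-cat meow vocalizations and for
    analysing how human listeners perceive them. Provides a synthetic generator
    for harmonic, frequency-modulated meow-like audio and for survey cohorts;
    framewise acoustic features (fundamental frequency with confidence gating,
    psychoacoustic roughness from a spectral partial-pair model, tristimulus
    timbre descriptors) aggregated to a per-recording feature space; a one-way
    ANOVA feature screen with centroid-based medioid/outlier exemplar selection;
    questionnaire scoring (Animal Empathy Scale, Cat Empathy Scale), context
    classification accuracy tables with chi-square and exact binomial chance
    tests, Mann-Whitney and Spearman analyses, Cronbach's alpha; and principal
    component analysis of emotion-descriptor ratings with a valence reading of
    the first component.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    yaml,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
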