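Package: astromorph
Title: Astrocyte Morphometry, Synapse Colocalization and RNA-FISH
    Quantification with Hierarchical Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification toolkit for astrocyte morphogenesis studies:
    filament-tree morphometrics (total branch length, 2D/3D Sholl
    intersection curves, convex-hull territory volume) from SWC
    reconstructions; pixel-based pre/post synaptic puncta colocalization
    and density normalized to astrocyte area; RNA-FISH expression scoring
    (mRNA puncta volume over soma volume) across cortical layers and
    developmental timepoints; and the matching hierarchical inference
    layer (mixed-model Sholl curve comparison with Tukey contrasts,
    nested t-test and ANOVA, two-way ANOVA with Dunnett reference
    contrasts, normality-gated nonparametric fallback, experiment-level
    quality control). A synthetic-data generator produces branching
    arbors, three-channel synapse stacks and full FISH study designs
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    lme4,
    lmerTest,
    emmeans,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
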