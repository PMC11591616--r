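Package: erpmicro
Title: Topographic Microstate Analysis of Event-Related Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Spatio-temporal segmentation of event-related potential (ERP)
    topographies into microstate maps and condition-level statistics.
    Implements reference-free topographic primitives (global field power,
    strength-independent spatial correlation), atomize-agglomerate
    hierarchical clustering (AAHC) of GFP-normalized grand-average
    topographies with multi-criterion selection of the number of maps and a
    minimum-duration temporal constraint, winner-take-all back-fitting of
    template maps to single-subject ERPs yielding per-map explained variance,
    field strength and duration, 2x2 repeated-measures ANOVA with partial and
    generalized eta squared, and an a-priori power calculator for
    within-factors designs based on the noncentral F distribution. A
    synthetic multi-subject, multi-condition ERP generator with planted
    microstate structure supports end-to-end validation against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
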