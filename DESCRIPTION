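Package: ctxbind
Title: Mixture Modeling and Inverted Encoding Analysis of Context Binding
    in Visual Working Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying context binding in visual working memory
    with continuous-report (delayed-estimation) tasks and fMRI. Implements
    maximum-likelihood fitting of two- and three-factor von Mises mixture
    models of recall error (target, non-target "swap", and uniform guess
    components), swap-error based subject grouping, boxcar GLMs with
    top-k voxel ROI selection and trial-averaged signal-change curves,
    inverted encoding models (IEM) of stimulus orientation and location
    with 180-point channel tuning function (CTF) reconstruction,
    exponentiated-cosine CTF quantification by grid search, and a bootstrap
    inference suite for reconstruction amplitudes, group differences, and
    recall specificity. A synthetic-data generator emulates balanced trial
    schedules, mixture-generated behavior, and channel-tuned voxel time
    series so the full pipeline is testable without scanner data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
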