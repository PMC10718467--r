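Package: audenc
Title: Voxelwise Encoding Models and Representational Similarity for Auditory Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Model-brain comparison toolkit for auditory fMRI. Implements a
    cochleagram front end (ERB-spaced cosine filterbank, Hilbert envelopes,
    compressive nonlinearity), a spectrotemporal modulation filterbank
    baseline, voxelwise ridge encoding models with leave-one-out
    regularization selection and a correction-for-attenuation noise ceiling,
    component-response prediction, representational similarity analysis with
    a leave-one-participant-out noise ceiling, best-stage hierarchy summaries,
    effective dimensionality, permuted-parameter control models, and the
    accompanying resampling statistics. A synthetic-data generator produces
    multi-stage feature hierarchies and voxel responses with known ground
    truth so the full pipeline can be exercised and validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
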