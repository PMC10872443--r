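Package: boldReliability
Title: Reliability and Longitudinal Inference for Densely Sampled Task fMRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variance-component reliability analysis for densely sampled
    (precision) task fMRI contrasts. Estimates pairwise test-retest
    intraclass correlations with meta-analytic pooling on the logit scale,
    voxel-level internal consistency from three-level multilevel models,
    and multilevel coefficient alpha; relates internal consistency to
    parcel size and residual smoothness with beta regression and
    leave-one-out predictive model comparison; and provides longitudinal
    within-person inference with cluster-robust (CR2) standard errors,
    Satterthwaite degrees of freedom, Freedman-Lane permutation nested
    within participants, max-cluster-extent familywise error control, and
    posterior sign-error-controlled parcel selection. A synthetic-data
    module generates voxel panels, behavioral predictor series, sleep and
    stress records, and NIfTI label volumes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    nlme,
    lme4,
    mgcv,
    splines,
    metafor,
    rjags,
    coda,
    RNifti,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
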