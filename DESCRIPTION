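Package: rnflcomp
Title: Covariate Compensation of Circumpapillary RNFL Thickness Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for normalizing 768-point circumpapillary retinal nerve
    fiber layer thickness (RNFLT) profiles for age, gender, axial length,
    disc-fovea distance, and disc-fovea angle.  A two-phase compensator first
    removes the age effect with a circularly smooth per-point slope field fit
    by penalized least squares, then removes ocular-geometry effects with a
    small fully connected network (global vertical scale and horizontal
    circular shift) followed by a radial basis function network that models
    the remaining smooth covariate-correlated residual.  Includes a synthetic
    cohort simulator with realistic covariate marginals, a normative-limit
    run-length glaucoma detection statistic, ROC/AUROC evaluation with
    axial-length percentile subgroups, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
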