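Package: simon2stage
Title: Inference After Simon's Two-Stage Phase II Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design search and post-trial inference for Simon's two-stage
    single-arm phase II designs with early stopping for futility. Provides the
    optimal and minimax design searches, the exact joint distribution of the
    stopping stage and total number of responses, seven point estimators of the
    response rate (MLE, Whitehead and Guo bias-corrected estimators, UMVUE,
    conditional MLE, UMVCUE, median-unbiased estimator), five p-values (naive,
    MLE ordering, stage-wise ordering, conditional, and conditional-power based),
    and seven confidence intervals (naive exact, exact and mid-p stage-wise,
    conditional exact, conditional score with continuity correction, conditional
    mid-p, and conditional-power based). Handles trials whose attained second
    stage sample size differs from plan via the conditional-power adjustment of
    the stage-2 critical value, and includes an exact-enumeration engine for
    bias, RMSE, rejection probability and coverage of every method, plus a
    Monte-Carlo trial simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
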