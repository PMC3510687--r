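Package: stimvarx
Title: Multivariate Autoregressive Modeling of Stimulation-Evoked
    Intracerebral Recordings
Version: 0.1.0
Authors@R:
    person("Jordan", "Mercer", email = "jmercer@example.org",
           role = c("aut", "cre"))
Description: Fits multivariate autoregressive models with an exogenous
    stimulus input (MVARX) to multichannel intracerebral recordings of
    responses to direct electrical stimulation. Provides stimulation
    artifact removal (Tukey-windowed median filtering), anti-alias
    filtering and downsampling, stimulus-aligned epoching, leave-one-out
    Mahalanobis outlier rejection, joint ordinary least squares
    estimation of connectivity and stimulus-filter parameters,
    cross-validated autoregressive order selection, a kernel-based
    portmanteau residual whiteness test, evoked-response reconstruction
    metrics, and Gaussian integrated-information analysis over network
    bipartitions. Includes a synthetic-data generator so the entire
    pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    optparse
Config/testthat/edition: 3
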