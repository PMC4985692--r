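Package: selbridge
Title: Conditional-Likelihood Estimation of Selection Coefficients from
    Single Allele-Frequency Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to estimate the selection coefficient acting on a
    two-allele locus from a single time series of allele counts under
    the Moran or Wright-Fisher model.  A single historical trajectory is
    pinned at both its initial and final value, so the appropriate
    likelihood is built from endpoint-conditioned (Doob h-transform)
    transition probabilities rather than from the raw model kernel.  The
    package constructs both chains' transition matrices, computes
    finite-horizon and asymptotic (quasi-stationary or
    absorption-conditioned) h-transforms, simulates unconditioned and
    bridge trajectories, evaluates and maximizes the conditional and
    unconditioned likelihoods, and orchestrates ensemble
    parameter-recovery experiments with mode and confidence-interval
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
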