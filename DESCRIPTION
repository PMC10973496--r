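Package: socialhmm
Title: Social Hidden Markov Decision Models for Collective Foraging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying social information use in freely moving
    groups of foragers. Implements a two-state hidden Markov movement model
    ("individual exploration" vs. "social relocation") with von Mises,
    normal and log-normal state-dependent distributions and covariate-
    dependent switching probabilities (visibility, distance, co-exploiter
    number and time since success), including monotonic time-varying
    effects, forward-algorithm likelihood, Viterbi decoding and a penalized
    maximum-likelihood / Laplace-approximation fitting backend with
    posterior-style contrasts, highest-density intervals and evidence
    ratios. Ships an agent-based simulator of a patchy-resource foraging
    arena (field-of-view visibility, shared patch depletion, respawning
    patches) that produces trajectories with known latent states, feature
    construction from raw tracks (turning angles, relative bearings,
    visibility-gated social channels, validity-masked segments), behavioral
    outcome metrics (scrounging rates, exploitation time-courses, spatial
    and visual summaries), and a time-lagged Gaussian-process binomial
    regression linking past group organization to current collective
    success.
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
    optparse
Config/testthat/edition: 3
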