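Package: tastecoda
Title: Population Coding Analysis of Gustatory Cortex Calcium Imaging Across
    Conditioned Taste Aversion
Version: 0.1.0
Authors@R:
    person("Martin", "Kowalczyk", email = "m.kowalczyk@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing single-cell calcium imaging of gustatory
    cortex recorded with head-mounted miniscopes while mice lick taste
    stimuli, before and after conditioned taste aversion (CTA). Provides
    trial-aligned response extraction (lick-anchored dF windows, +/-3 SD
    responsiveness calls, cross-day tracked-cell filtering), breadth-of-tuning
    entropy and stimulus-best unit assignment, population geometry via
    principal coordinates analysis with Euclidean-distance trajectories and
    Lance-Williams complete-linkage clustering, linear support-vector-machine
    decoding of stimulus identity and palatability (leave-one-out
    cross-validation, shuffled-label nulls, bootstrap, train-pre/test-post),
    lickometer behavioural analytics, and a synthetic-cohort generator with
    known ground truth that emulates the full session schedule so every stage
    can be exercised and validated without original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
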