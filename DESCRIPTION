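Package: molclock
Title: Neutral Molecular Clock Rates in Spatially Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes site-specific and overall fixation probabilities of
    neutral mutations for populations with arbitrary spatial (replacement)
    structure, represented as weighted digraphs of per-time-step replacement
    probabilities. From the solved fixation system it derives the neutral
    substitution rate per generation (K) and per time-step, classifies
    structures by the conditions under which spatial structure leaves the
    molecular clock unchanged, slows it, or accelerates it, and provides
    exact closed forms for small populations and standard families (star,
    hub-and-leaves, upstream-downstream). A Monte-Carlo engine simulates the
    underlying evolutionary and ancestral Markov chains over replacement
    events as an independent stochastic check. A network pipeline ingests
    directed follower graphs (edge lists), applies centrality-based pruning,
    and computes substitution rates of neutrally spreading ideas across an
    ensemble of networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
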