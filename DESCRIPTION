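Package: collrep
Title: Collective Reputations and Indirect Reciprocity in Public Goods Games
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulation of indirect reciprocity in public goods
    games where observers judge a recipient group through its collective
    reputation: a group is deemed good when the fraction of members the
    observer privately considers good reaches an assessment criterion
    (threshold) lambda. Implements the leading-eight social norms plus
    unconditional cooperation and defection as explicit assessment/action
    tables, private image-matrix reputation dynamics with observation and
    perception noise, and the evolutionary layer: Fermi (pairwise-comparison)
    imitation, composition-dependent expected payoffs, closed-form fixation
    probabilities of the imitation birth-death chain, the rare-mutation
    embedded Markov chain and its selection-mutation equilibrium, the critical
    payoff parameter for unconditional cooperation, and scans over payoff and
    strictness that locate the assessment criterion most conducive to
    cooperation in social dilemmas.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
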