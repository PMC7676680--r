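Package: foodchainsim
Title: Agent-Based Simulation of Resilience and Efficiency in Food Supply Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time agent-based simulator of stylized food supply
    chains in which producers sell crops to traders and consumers buy from
    traders over a strictly layered trade network. Partner selection follows
    random, stock-weighted, or trust-constrained (preference) interaction
    rules, and production, trader, or consumer shocks perturb the system.
    The package quantifies consumer satisfaction, the relative impact of
    shocks, and the information-theoretic decomposition of time-averaged
    trade flows into total capacity, efficiency (ascendency), and resilience
    (reserve), and ships factorial and one-factor-at-a-time experiment
    drivers plus a command-line interface for batch studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
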