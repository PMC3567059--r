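Package: schoolnet
Title: Generative Models and Statistical Validation for Elementary-School
    Friendship and Enmity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generators for classroom-confined social network topologies:
    the School Friendship Network model (per-classroom random blocks with
    sense-of-belonging subgrouping and shortcut rewiring, yielding
    Poisson-like degrees with high clustering) and the School Enmity
    Network model (per-classroom preferential attachment over a fixed
    roster, yielding power-law-tailed degrees with isolated students).
    Includes the nine standard network measurements with conventions for
    disconnected graphs, Erdos-Renyi / Watts-Strogatz / Barabasi-Albert
    reference models with their closed-form degree laws, a statistical
    validation toolkit (Poisson chi-square goodness of fit, discrete
    power-law tail fitting with bootstrap Kolmogorov-Smirnov p-values,
    log-log regression), batch replicate running, and construction of
    symmetric friendship/enmity/kinship adjacency matrices from
    sociometric nomination surveys with rule-based kinship closure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
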