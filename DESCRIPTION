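Package: encounternets
Title: Encounter Networks from Long-Range Random Walks and Geotagged Check-Ins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how temporal encounter (contact) networks emerge
    from human mobility. Implements a long-range (Levy-flight-like) discrete
    random walk on a fixed set of spatial locations, its exact spectral
    characterization (stationary distribution, mean return and first-passage
    times), and the construction of temporal encounter networks from
    co-locations of many independent walkers under a finite memory window and
    a minimum-contact threshold. A companion empirical pipeline parses
    geotagged check-in streams, fits heavy-tailed inter-event time and
    displacement distributions by maximum likelihood with a
    Kolmogorov-Smirnov cutoff scan, detects hourly proximity co-coincidences
    between users, and summarizes the resulting cumulative encounter
    networks. A synthetic check-in generator with planted power laws and
    shared hotspots makes the whole pipeline testable without any external
    data set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    Matrix,
    igraph,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
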