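Package: coclique
Title: Coclique Level Structures and Mean First Passage Time Bounds for
    Stochastic Chemical Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and enumerates coclique level functions of the projected
    continuous-time Markov chain associated with a unit-transfer stochastic
    chemical reaction network (SCRN), i.e. integer-linear functions whose level
    sets partition the state space into cocliques. Provides exact rational
    computation of stoichiometric rank and conservation laws, graph-based
    existence criteria (bipartiteness, weakly directed cycle obstructions),
    an enumeration algorithm over canonical edge partitions, construction of
    sparse generators on the conservation simplex, and closed-form birth-death
    upper and lower bounds for mean first passage times between extreme level
    sets, validated against exact sparse linear solves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
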