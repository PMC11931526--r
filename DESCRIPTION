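Package: ejecta
Title: Sputtered-Ejecta Census and Electron Track Monte Carlo for
    Water-Cluster SIMS Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Post-processing of reactive molecular-dynamics trajectories of
    massive water-cluster impacts on molecular solids, aimed at the mechanism
    of secondary-ion yield enhancement in cluster-SIMS. Identifies molecules
    as connected components of the bond-order graph, assembles contact-based
    clusters, decomposes the sputtered yield into bare/solvated/fragment
    categories in trehalose-mass units, tracks the lifetime of
    (single trehalose)-water complexes through an extended flight phase, and
    runs a table-driven Monte Carlo of low-energy electron transport in
    nanoscale ice spheres to obtain hydronium-count distributions for singly
    charged projectiles. A synthetic-scene generator with planted ground
    truth supports end-to-end validation without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
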