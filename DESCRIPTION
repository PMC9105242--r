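Package: oilcluster
Title: Clustering, Structure and Association Dynamics of Polymer-Terpenoid
    Solutions from Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for molecular dynamics trajectories of
    small hydrophobic solutes (terpenoid essential-oil ingredients) mixed
    with hyperbranched polymer drug carriers in water. Provides
    periodic-boundary-aware DBSCAN clustering of molecular centers of mass,
    center-of-mass radial distribution functions with a long-range
    (Theodorou-Suter style) extension beyond half the box length,
    coordination numbers and first-shell detection, self and distinct van
    Hove correlation functions, mean square displacement with
    Einstein-relation self-diffusion, geometric hydrogen-bond detection with
    intermittent autocorrelation and integrated lifetimes, a
    periodic-boundary-aware swarm radius of gyration, and composition
    bookkeeping for the simulated systems. A seeded Brownian/Langevin
    synthetic-trajectory generator with known ground truth supports testing
    every analysis stage without simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
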