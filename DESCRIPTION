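Package: orbweb
Title: Multibody Dynamic Simulation of Orb-Web Prey Impact Under Climate Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a node/link model of a spider orb web from measured
    geometric parameters, assigns silk material properties per thread class,
    and simulates the impact of a flying-prey projectile as a tension-only
    linear-spring multibody system with pretension, lumped silk masses,
    gravity, axial damping, sphere-thread penalty contact and permanent
    thread breakage. Humidity and temperature effects on major ampullate
    silk are applied as percentage transforms of stiffness and breaking
    strain, and a scenario-by-impact-point sweep aggregates trajectories,
    thread strain distributions, broken-thread counts and peak strain-energy
    summaries with full energy accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    parallel,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
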