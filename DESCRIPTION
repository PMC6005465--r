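Package: condensim
Title: Coarse-Grained Simulation of Condensin-Driven Chromosome Shaping
    and Segregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bead-spring polymer simulator of mitotic chromosomes with
    condensin point particles. Condensins hold consecutive chromatin loops
    by harmonic bonds and attract one another within a finite range;
    chromatin monomers interact through a capped Weeks-Chandler-Andersen
    excluded-volume potential and phantom harmonic springs. The package
    provides a Langevin-thermostatted velocity-Verlet integrator, a
    deterministic loop-extrusion initializer that installs crossed loops,
    order parameters for chromosome shaping (gyration-tensor asphericity)
    and segregation (loop-sphere overlap, trans-/cis-attraction fractions,
    segregation speed, condensin-axis radial density), and a config-driven
    experiment runner with parameter sweeps and replicate averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
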