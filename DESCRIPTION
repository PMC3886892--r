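Package: memdimer
Title: Free-Energy Landscapes of Restrained Membrane-Protein Dimerization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to reconstruct and analyse the free-energy landscape of
    lateral association (dimerization) of membrane proteins from umbrella
    sampling: harmonic centre-of-mass-separation biases and torque-only
    orientational restraints, potential-of-mean-force (PMF) reconstruction
    by the weighted histogram analysis method (WHAM) with histogram-overlap
    diagnostics and split-half convergence assessment, quadratic location
    of restrained (meta)stable minima and desolvation-like barriers,
    prediction of lipid-packed metastable separations from the annular
    lipid density around a single protein, and lipid-probe buried
    surface-area analysis versus well depth.  A seeded quasi-2D Langevin
    toy membrane (two rigid elliptical bodies in a sea of repulsive lipid
    discs) and exact 1D Boltzmann reference systems make every stage of
    the pipeline testable without external trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
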