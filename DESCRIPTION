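Package: corofsi
Title: Reduced-Order Fluid-Structure Interaction for Coronary Artery Biomechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Artery-specific simulation of coronary haemodynamics and wall
    mechanics under cyclic bending. Builds vessel motion from diastolic and
    systolic centreline pairs, solves coupled pulsatile non-Newtonian
    (Carreau) blood flow and Ogden hyperelastic wall mechanics with
    backward-incremental physiological pre-stress on a reduced-order
    structured tube discretisation, and computes the shear and strain
    metrics (TAWSS, transverse shear stress, OSI, cyclic logarithmic
    strain, bending derivative) used to quantify the biomechanical effect
    of coronary bending. Includes a seeded synthetic-data generator for
    coronary-like geometries, waveforms and motion so that the full
    pipeline runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
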