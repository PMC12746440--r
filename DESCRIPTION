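Package: rayoa
Title: Rayleigh Optical Activity Invariants, Circular Intensity
    Differentials, and Scattered Circular Polarization Measurement
    Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the rotational invariants of molecular property
    tensors (the electric dipole-electric dipole polarizability, the
    electric dipole-magnetic dipole optical activity tensor, and the
    electric dipole-electric quadrupole tensor) and from them the
    circular intensity differential measured in scattered circular
    polarization (SCP) Rayleigh optical activity at right angles in the
    depolarized geometry. Includes the exact spatial transformation
    group for property tensors (rotations, the enantiomer map, origin
    shifts), wavelength rescaling of predictions, a photon-counting
    simulator of the SCP measurement with shot noise and the standard
    correction pipeline (enantiomeric excess, incident-beam optical
    rotation, enantiomer-independent offset), absolute-configuration
    assignment by sign comparison against prediction ensembles, and a
    seeded generator of synthetic chiral tensor sets for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
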