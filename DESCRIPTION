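Package: qhmd
Title: Quantum Hamilton Trajectories for Diatomic Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: State-dependent molecular dynamics of diatomic molecules via
    quantum Hamilton mechanics: complex Bohmian trajectories for vibration,
    rotation and spin in rovibrational eigenstates of the Morse oscillator
    under the Pekeris approximation. Provides the analytic eigensystem
    (radial Morse-Laguerre and first/second-kind associated Legendre
    wavefunctions at complex argument), complex-trajectory integration with
    conserved-quantity diagnostics, state-dependent equilibrium bond lengths,
    vibration periods by three independent routes, force constants,
    spin-region classification of complex angular trajectories, and
    rigid-rotor, centrifugal-distortion and trajectory-based rotational
    spectra, with built-in parameter sets for H2, HCl, O2 and N2 and the
    measured HCl far-infrared line list.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
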