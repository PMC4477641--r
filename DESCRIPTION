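Package: tpmbend
Title: DNA Bend Angles from Tethered Particle Motion Data
Version: 0.1.0
Authors@R:
    person("TPM", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measurement of local DNA bend angles from Tethered Particle
    Motion (TPM) experiments. Implements a kinked Worm-Like-Chain (WLC)
    model of the tethered DNA, camera-blur and particle-size corrections
    that convert tracked bead amplitudes of motion into DNA end-to-end
    distances, least-squares fitting of phased bend series to extract the
    per-repeat bend angle, a closed-form single-site angle inversion with
    a detection floor, a heterogeneous-rigidity WLC correction, an
    equilibrium Metropolis Monte Carlo simulator of the wall-tethered
    bead-DNA assembly, trajectory reduction (anchor, drift, amplitude,
    correlation time, asymmetry), and synthetic data generators with
    known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
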