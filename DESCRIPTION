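Package: driftcode
Title: Retinal Coding and Ideal-Observer Acuity Under Fixational Eye Movements
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates ocular drift during fixation as a two-dimensional
    Poisson-step diffusion on a discrete grid, encodes moving Snellen-E
    optotypes with a linear-nonlinear Poisson model of the foveal retinal
    ganglion cell mosaic, and decodes stimulus orientation with a recursive
    Bayesian ideal observer that marginalizes over the unknown stimulus
    position. Includes trajectory statistics (diffusion-coefficient
    estimation, power spectra, mean-square displacement, path lengths and
    rank-based comparisons across stimulus sizes), a synthetic generator for
    drift trajectories and subject profiles in a documented CSV dialect, and
    experiment drivers that map discrimination accuracy as a function of
    drift amplitude and stimulus size in a four-alternative forced-choice
    task.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
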