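Package: retinomap
Title: Photoreceptor-Selective Retinotopic Mapping and Silent-Substitution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing cone- and rod-mediated retinotopic maps
    measured with photoreceptor-selective (silent-substitution) stimuli.
    Includes display calibration and receptor-isolating chromatic pair
    solvers, combined ring-and-wedge aperture protocol generation,
    population receptive field (pRF) model prediction and two-stage
    coarse/fine fitting with cortical surface smoothing, rod-cone map
    correspondence statistics (orthogonal regression, Akaike weights,
    Fisher-Lee circular correlation), visual field coverage and pRF
    size-by-eccentricity profiling, adaptive staircase psychophysics
    simulation, and a synthetic cortical sheet generator so the whole
    pipeline can be exercised end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
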