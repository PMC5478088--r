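Package: shadowtrack
Title: Shadowing-Filter Trajectory Reconstruction for Animal Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Batch reconstruction of the closest Newtonian trajectory
    (position, velocity and piecewise-constant acceleration) to noisy,
    gappy, irregularly sampled position fixes such as GPS telemetry from
    flying birds.  Implements the shadowing filter as a
    Newtonian-constrained least-squares problem solved by singular value
    decomposition, selection of the smoothing weight from the device
    noise variance or by replicated simulation sweeps, a windowing test
    for the minimum observation window, a sliding-average plus
    finite-difference baseline for comparison, a synthetic track
    generator emulating high-rate GPS data with dropouts, and CSV
    readers/writers with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
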