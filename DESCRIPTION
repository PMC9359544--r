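Package: mocapfill
Title: Missing-Marker Recovery for Motion Capture Data by Locally
    Weighted PCA Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fills gaps in 3D skeletal motion-capture trajectories.
    Implements a family of PCA regression methods that learn, from training
    motion samples, per-gap eigenspace mappings between the subspace of
    complete motion and the subspace of motion corrupted with the same gaps
    as the test sample.  A residual-eigenvalue weight matrix turns the fit
    into a weighted least-squares problem, and an optional Gaussian taper
    mask over the skeleton graph localises the regression around each gap
    (covariance tapering).  A Gram-matrix (frame-space) variant recovers
    whole missing frames.  Includes readers and writers for TRC and CSV
    marker-trajectory files, a seeded synthetic motion generator with
    configurable skeleton topology and gap-placement protocols, simple
    interpolation and self-PCA baselines, and a trial-averaging evaluation
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    MASS,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
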