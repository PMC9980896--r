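Package: neomotion
Title: Head-Motion Quality Control and Censoring Evaluation for Neonatal
    Resting-State fMRI Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the impact of head motion on resting-state
    functional connectivity in neonatal fMRI. Computes frame-wise displacement
    from 6-parameter rigid-body motion estimates, builds volume-censoring
    (scrubbing) plans with threshold and scan-length capping, performs
    simultaneous nuisance regression and band-pass filtering, computes temporal
    signal-to-noise ratio, derives Fisher z-transformed region-of-interest
    connectivity (homotopic strengths, whole-connectome edges, seed maps), and
    quantifies motion-connectivity associations: motion-group contrasts with
    false-discovery-rate control, distance-dependence analyses, and bootstrap
    partial-correlation tests of age effects controlling for motion. Includes a
    synthetic-cohort generator with known ground-truth covariance,
    motion-coupled artifacts and noise, so every stage is testable end to end
    without access to clinical scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
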