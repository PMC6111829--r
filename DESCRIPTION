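Package: iicp
Title: Improved Iterative Closest Point Registration for Surface Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rigid registration of 3-D surface point clouds with an improved
    iterative closest point (I-ICP) algorithm: median-based correspondence
    weighting damps wrong matches from non-overlapping regions, and a
    stochastic parabolic perturbation with golden-section refinement restarts
    the search to escape locally optimal alignments. Includes a classic
    point-to-point ICP baseline, weighted least-squares (Kabsch) transform
    estimation, target registration error (TRE) evaluation at labelled
    fiducial markers, readers and writers for PLY, PCD and XYZ point clouds,
    and a synthetic scan generator with known ground truth emulating
    CT-surface to depth-sensor registration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
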