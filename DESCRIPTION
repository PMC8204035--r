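Package: erupt3d
Title: Registration-Based Quantification of Maxillary Canine Eruption from Paired CBCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies three-dimensional tooth eruption between two cone-beam CT time
    points. A follow-up scan is rigidly registered onto the baseline scan by mutual-
    information maximization restricted to a stable bony region of interest, teeth are
    delineated by livewire contouring with shape-based contour interpolation (or by
    thresholding), and the rigid motion between the pre- and registered post-operative
    tooth surfaces is recovered by iterative-closest-point registration and decomposed
    into six clinically named degrees of freedom: mesiodistal, palatofacial and
    incisoapical translation plus pitch, roll and yaw. Includes surface distance-map
    validation of the registration (mean absolute difference), intraclass-correlation
    and Wilcoxon signed-rank reliability statistics, and a synthetic phantom generator
    producing paired CBCT-like volumes with known ground-truth motions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    EBImage,
    mgcv,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
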