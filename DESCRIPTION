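Package: stentgeom
Title: Geometric Morphometry of Bridging Stents After Branched Endovascular
    Aortic Repair
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Centerline-based geometric analysis of bridging stent-grafts
    placed during branched endovascular aortic repair (B-EVAR): take-off
    angle of target vessels, perpendicular cross-section shape index
    (minimum over maximum Feret diameter), three-zone stent decomposition
    with per-zone lengths and mean shape index, longitudinal stent
    shortening against nominal length, and the cohort-level statistics
    (t-tests, one-way ANOVA, Pearson correlation, intraclass correlation)
    used to compare stent types.  Includes a synthetic phantom generator
    (tubular meshes, voxel label maps, simulated cohorts) with analytically
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    igraph,
    RNifti,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
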