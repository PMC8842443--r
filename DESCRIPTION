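Package: capillux
Title: Retinal Capillary Hemodynamics and Retinal Thickness from Line-Scan
    and OCT Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantification pipeline for in-vivo retinal capillary
    hemodynamics and retinal thickness in the mouse. Computes red blood
    cell flux, instantaneous velocity and stall status from space-time
    (kymograph) line-scan images and grader cell markers; capillary lumen
    diameter from boxed RBC width measures with vessel-angle and
    age-magnification correction; eye motion by one-dimensional line-scan
    registration; total retinal thickness by graph shortest-path
    segmentation of OCT B-scans; and the cohort statistics layer
    (hyperglycemia designation, stall rates, Bland-Altman agreement with
    exact tolerance-factor confidence intervals, group comparisons,
    regressions). A synthetic-data generator emulates the acquisition with
    known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
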