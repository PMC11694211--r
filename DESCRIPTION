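Package: snatchkin
Title: Barbell Kinematics, Kinetics and Study Statistics for the Olympic Snatch
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes barbell motion-capture and force-plate recordings of the
    Olympic snatch into the discrete kinematic and kinetic parameters used to
    monitor technical efficiency (peak velocity and height, anteroposterior
    displacements X1/X2/X3 and their derived ranges, vertical ground reaction
    force, rate of force development and power), classifies the barbell path
    against the optimal toward-away-toward pattern, and runs the
    repeated-measures statistical battery (Shapiro-Wilk gate, RM-ANOVA or
    Friedman omnibus with Bonferroni-corrected post hocs) across learning
    conditions, including a-priori noncentral-F power analysis. A synthetic
    trial and cohort generator with known ground truth supports end-to-end
    validation without laboratory data.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
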