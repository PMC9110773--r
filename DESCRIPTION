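Package: lvmass
Title: Echocardiographic Left Ventricular Mass Quantification and Method Agreement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies left ventricular mass (LVM) from traced two-dimensional
    echocardiographic contours and linear measurements using five methods: the
    Devereux cube formula, Area-Length, Truncated Ellipsoid, biplane
    endocardial/epicardial tracing, and a two-dimensional method that adds the
    mean wall thickness derived from the parasternal short-axis view to each
    disk of the biplane method of disks. Includes the geometric primitives
    (shoelace areas, long-axis and chord-stack decomposition, Teichholz
    volumes), a method-agreement statistics protocol (bias and 95% limits of
    agreement, coefficient of variation, standard error of the estimate,
    Pearson correlation, paired t-test, proportional-bias regression,
    per-subject accuracy ranking, reader variability), and a synthetic phantom
    generator producing truncated prolate-spheroid left-ventricular shells with
    analytically known mass, rendered to view contours under a tracing-noise
    model, so every method and statistic can be validated without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
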