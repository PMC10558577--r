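Package: implantsize
Title: Dental Implant Size Classification from Radiographic Key Points
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies bone level dental implants into nine catalogue sizes
    (diameters 3.3/4.1/4.8 mm by lengths 8/10/12 mm) from three key points
    annotated on periapical radiographs. Key-point triples are converted to
    radiographic diameter and length in millimetres via triangle geometry and
    the imager pixel spacing, weighted along the diameter axis, and clustered
    with k-means++ (k = 9) into size groups. Includes one-vs-rest performance
    evaluation (accuracy, sensitivity, specificity, F1, PPV, NPV, single
    operating point AUC with DeLong confidence intervals, chi-square model
    comparison), a synthetic annotation generator emulating radiographic
    magnification and angular foreshortening, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
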