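Package: clavsim
Title: Virtual Placement and Screw-Coverage Analysis of Lateral Clavicle Locking Plates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A simulation workbench for comparing lateral-clavicle locking
    plates. Generates a parametric population of synthetic clavicle surface
    meshes, constructs three locking-plate fixtures with product-specific
    screw fan geometries, measures projected coronal/sagittal screw fan
    angles through the plate coordinate system, automatically seats each
    plate as far laterally as possible without encroaching on the
    acromioclavicular joint, counts screws completely contained in simulated
    lateral fragments of 10-30 mm, measures the screw-covered area on the
    inferior cortex, and analyzes the results with paired TOST equivalence
    testing, Steel-Dwass all-pairs comparisons, and Tukey HSD.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
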