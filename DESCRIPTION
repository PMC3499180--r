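Package: growthplate
Title: Finite-Element Simulation of Mechanically Modulated Growth-Plate
    Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates longitudinal bone growth driven by chondrocyte
    proliferation and hypertrophy in the growth plate, with mechanical
    modulation of cellular activity by sustained axial stress
    (Hueter-Volkmann behaviour: compression retards growth, distraction
    promotes it).  The growth plate is represented as a five-region
    two-dimensional plane-strain domain (trabecular bone, reserve,
    proliferative and hypertrophic cartilage) discretised with four-node
    quadrilateral finite elements; tissue growth enters as a rank-one
    strain-rate tensor along the columnar growth direction, assembled from
    cell-level proliferation and hypertrophy kinetics.  Ships the complete
    rat proximal-tibia parameter set (tissue moduli, zone thicknesses,
    cells per column, hypertrophic cell heights and time intervals for
    sustained stress differences of -0.2 to +0.1 MPa) and reproduces the
    23-day growth-rate validation for those four load cases.  Results are
    exported as CSV time series and VTK unstructured-grid snapshots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
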