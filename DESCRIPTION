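Package: IsletRadius
Title: Quantification of Endocrine Cell Localization in Pancreatic Islets
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-automated quantification of hormone-positive cell
    localization and distribution in pancreatic islets of Langerhans from
    stained section images. Detects hormone-positive pixels in
    immunohistochemical (DAB) colour images by HSV thresholding and in
    immunofluorescence images by intensity thresholding, then computes each
    pixel's relative radius with respect to a user-supplied islet boundary
    polygon via polar transformation and angular linear interpolation.
    Provides per-islet summaries (mean relative radius, relative area,
    exclusion accounting), a batch pipeline with CSV and XLSX export, and a
    synthetic stained-islet generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    EBImage,
    zip
Suggests:
    testthat (>= 3.0.0),
    readxl,
    mgcv,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
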