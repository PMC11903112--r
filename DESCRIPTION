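Package: lobmorph
Title: Nuclear Morphometry of Lobular Carcinoma Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative nuclear morphometry of breast lobular
    carcinoma variants. Reads nucleus boundaries from QuPath-style GeoJSON
    detections or integer label masks, computes the four calibrated nuclear
    size parameters (area, perimeter, minimum and maximum Feret diameter),
    summarises them per case and per variant as median/quartile/IQR tables,
    expresses lesions as size ratios to reference cells (lymphocytes, normal
    epithelium, grade-matched carcinoma of no special type), derives ROC
    cut-offs by the Youden index, applies a published median/IQR cut-off rule
    set separating the pleomorphic variant from classic and solid variants,
    and fits multivariable logistic models. A synthetic nucleus-population
    generator calibrated to published quartile tables makes the whole
    pipeline testable without whole-slide images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    tibble,
    stats,
    grDevices,
    utils,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
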