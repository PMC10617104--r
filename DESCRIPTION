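Package: uclga
Title: Myometrial Infiltration Depth from Uterine Cavity Line Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-aided measurement of myometrial infiltration (MI) depth
    of early endometrial cancer on sagittal image slices. Fits an ellipse to
    the segmented uterine contour by the direct least-squares method under the
    ellipse constraint 4ac - b^2 = 1, takes the major axis as a virtual
    uterine cavity line (UCL), casts perpendicular rays from the UCL to
    measure tumor penetration as a fraction of local myometrial thickness,
    and classifies FIGO stage IA versus IB at the 0.5 threshold. Includes a
    synthetic phantom generator with known ground-truth geometry, detection
    confidence based slice selection, invertible crop-and-pad coordinate
    transforms, pluggable detector/segmenter backends, and evaluation
    statistics (IoU, pixel accuracy, Dice, average precision, ROC/AUC and the
    DeLong paired-AUC test).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
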