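Package: gaitrait
Title: Psychological Trait Prediction from 2D Video Gait Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline from OpenPose BODY25 2D keypoint streams to
    psychometric trait prediction. Walking bouts recorded at 25 Hz are
    preprocessed (face-toward segment selection, MidHip re-referencing,
    binomial Gaussian smoothing, fixed 75-frame standardization), turned
    into a 2,472-dimensional gait feature vector (time-domain summary
    statistics over raw, inter-frame difference, inter-joint distance and
    inter-joint angle series, plus five-level Haar wavelet band
    statistics), and regressed onto a trait score with sequential forward
    feature selection and seven regression algorithms under 10-fold
    cross-validation. Includes odd-even split-half reliability of model
    predictions, indicator-level weight analysis, and a synthetic
    articulated-walker simulator so the whole pipeline is testable
    without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    e1071,
    kernlab,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
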