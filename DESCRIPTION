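Package: emaclass
Title: Automated Classification of IgA Endomysial Antibody Immunofluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Texture-based classification of IgA-class endomysial antibody (EmA)
    indirect immunofluorescence images into the four diagnostic classes used in
    celiac disease serology (positive, negative, IgA deficient, equivocal).
    Implements a multi-scale rotation-invariant co-occurrence local binary
    pattern descriptor computed on the green fluorescence channel after unsharp
    edge enhancement, one-vs-all radial-basis support vector machine and boosted
    decision tree classifiers with repeated stratified 70/30 evaluation,
    random under-sampling for class imbalance, and the full evaluation surface
    (confusion matrix, accuracy, sensitivity, specificity, F1, Cohen's kappa,
    one-vs-all ROC/AUC). Includes a seeded synthetic immunofluorescence image
    generator so the pipeline can be exercised end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jpeg,
    jsonlite,
    png,
    rpart,
    stats,
    tiff,
    tools,
    utils
Suggests:
    caret,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
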