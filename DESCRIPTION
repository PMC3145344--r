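Package: ecgbeats
Title: Interpatient Heart-Beat Classification with Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for supervised, interpatient classification of ambulatory
    ECG heart beats into the AAMI classes (normal, supraventricular ectopic,
    ventricular ectopic, fusion). Implements a 249-column per-beat feature
    extractor (segmentation, R-R interval, morphological, Hermite basis
    expansion, higher-order cumulant, and patient-normalized feature groups),
    class-weighted linear discriminant analysis and class-weighted
    one-against-one polynomial-kernel support vector machines for unbalanced
    classes, histogram mutual-information feature ranking, forward-backward
    wrapper feature selection, and a balanced-classification-rate evaluation
    protocol with patient-disjoint train/test splits and leave-one-patient-out
    hyperparameter search. A fully seeded two-lead synthetic ECG generator
    with ground-truth fiducial points makes the whole pipeline testable
    without access to clinical recordings. Readers and writers are provided
    for a WFDB-style dialect (format-212 signals, MIT binary annotations) and
    a plain CSV dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
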