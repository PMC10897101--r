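Package: ventsync
Title: Automated Characterization of Patient-Ventilator Interaction from
    Surface Electromyography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects inspiratory patient efforts in respiratory surface
    electromyography (sEMG), segments ventilator insufflations from the
    airway pressure waveform, classifies each breath's patient-ventilator
    interaction into six classes (synchronous, delayed, auto-trigger,
    ineffective, double trigger, double effort) and computes an asynchrony
    index. Includes esophageal-pressure (Pes) preprocessing with
    chest-wall-elastance correction to derive the muscular pressure Pmus,
    validation metrics against expert references (detection sensitivity and
    positive predictive value, per-class confusion tables, repeated-measures
    Bland-Altman limits of agreement) and a synthetic ventilated-patient
    signal generator with scripted asynchrony scenarios and exact ground
    truth, so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
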