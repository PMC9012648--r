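Package: abrref
Title: Reference Method Comparison for Click-Evoked Auditory Brainstem Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the EEG reference choice shapes click-evoked
    auditory brainstem response (ABR) waveforms. Implements a three-shell
    spherical head model with a truncated Legendre-series lead field, the
    reference electrode standardization technique (REST) for approximate
    infinity re-referencing, the conventional average-reference and
    mean-mastoid transforms, a stimulus-locked epoching and averaging chain,
    wave I/III/V peak quantification, and a synthetic-data generator that
    emulates a 32-channel, 20 kHz ABR acquisition so the whole pipeline is
    verifiable without human recordings. Minimal EDF+ import/export is
    included for real multichannel recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, graphics, grDevices, signal, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'abrref-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'montage.R'
    'leadfield.R'
    'template.R'
    'simulate.R'
    'preprocess.R'
    'rereference.R'
    'metrics.R'
    'edf.R'
    'pipeline.R'
    'show-methods.R'
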