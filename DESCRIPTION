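Package: sersdx
Title: Chemometric Classification of SERS Blood Spectra by OSC-PLS-DA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end chemometrics pipeline for diagnostic classification of
    surface-enhanced Raman (SERS) spectra of blood fractions: rubberband
    (convex-hull) baseline correction, normalization, Savitzky-Golay second
    derivative, spectral region selection, orthogonal signal correction (OSC)
    followed by PLS discriminant analysis, leverage/studentized-residual outlier
    screening, leave-one-out cross-validation (SECV), external validation (SEP),
    and ROC/AUC evaluation. Includes a synthetic SERS cohort generator with
    Lorentzian band models, fluorescence baselines and replicate structure so the
    whole pipeline is testable without patient data, plus readers for wide-table
    CSV and JCAMP-DX spectra.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, signal, jsonlite
Suggests: testthat (>= 3.0.0), pROC, mixOmics, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
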