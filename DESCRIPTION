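Package: simcaGC
Title: Peak Identification and SIMCA Class Annotation for GC/MS Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Mines aligned GC/MS metabolomics peak tables for metabolite
    information. Retention times of a reference library are updated from
    user-chosen pseudo-internal standards, peaks are identified by the
    weighted Pearson correlation (degree of coincidence) of electron-
    ionization spectra within a retention-time window, and peaks that match
    no library entry are annotated with a chemical class by soft independent
    modeling of class analogy (SIMCA): one principal-component model per
    class, membership decided by an F-test on residual standard deviations.
    The result is an organized peak-by-sample matrix with no missing values.
    Includes seeded synthetic-data generators so the whole pipeline is
    testable without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
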