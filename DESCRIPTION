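Package: supcorr
Title: Correction of Intensity-Dependent Ion Suppression in LC-FTMS
    Peptide Elution Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates and corrects intensity-dependent signal suppression in
    peptide elution profiles from liquid-chromatography Fourier-transform mass
    spectrometry (LC-FTMS). The carbon isotope pattern of a peptide fixes the
    theoretical intensity ratio between its monoisotopic (12C) and first heavy
    (13C) species; departures of the observed ratio from theory identify the
    suppression, and an iterative conditional-mode procedure recovers a
    monotone correction function per peptide. Libraries of estimated
    distortion functions are then used to predict fold-change null
    distributions at any intensity level, so that measured fold changes in
    label-free differential experiments can be assigned empirical
    significance P-values. Includes an mzXML reader, extracted-ion
    chromatogram and peak-interval preprocessing, a ground-truthed synthetic
    data generator, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mzR,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
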