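Package: fhrpet
Title: Regional FDG-PET Quantification and Forebrain-to-Hindbrain Ratio
    Prognostication for Post-Cardiac-Arrest Brain Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying small-animal FDG-PET brain scans against a
    volume-of-interest (VOI) label atlas and deriving prognostic indices for
    post-cardiac-arrest syndrome (PCAS). Converts activity-concentration
    volumes to standardized uptake values (SUV), reduces them to per-region
    means with hemisphere averaging and subregion merging, and computes SUV
    change between timepoints, whole-brain-normalized SUV ratios (SUVR), and
    the forebrain-to-hindbrain ratio (FHR). Outcome labels are assigned from
    Morris water-maze performance; groups are compared with exact
    nonparametric tests, and the prognostic value of the FHR is assessed by
    ROC analysis with a Youden-optimal cutoff. Because per-animal scans from
    the motivating cardiac-arrest studies are not public, the package
    includes a calibrated digital rat-brain phantom and cohort simulator
    reproducing published regional uptake distributions, so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
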