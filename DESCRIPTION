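Package: ppipet
Title: Behavioral PET Analysis of Prepulse Inhibition of Acoustic Startle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing prepulse inhibition (PPI) of the acoustic
    startle reflex combined with behavioral FDG-PET in rodents. Provides
    startle-session construction and trial-level amplitude quantification
    (PPI percentages, startle/PPI event classification, relative event
    difference), brainstem auditory evoked potential (BAEP) threshold
    estimation, reference-region (ratio) intensity normalization of PET
    volumes, voxelwise paired-t, repeated-measures ANOVA/Tukey q, and
    Pearson correlation maps with empirical noise-floor estimation by
    random split-half and hemisphere-flip null comparisons, and a
    synthetic-phantom cohort generator with known ground truth for
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
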