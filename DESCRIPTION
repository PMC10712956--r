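Package: mitotherm
Title: Mitochondrial Temperature Inference from Fluorescence Thermometry Traces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for inferring mitochondrial temperature from fluorimeter
    time series recorded with temperature-sensitive probes: the single-channel
    dye Mito Thermo Yellow (MTY) and the genetically encoded ratiometric
    reporter pair mito-gTEMP (mT-Sapphire/Sirius). Provides plateau and
    stability detection, per-experiment internal step calibration against
    imposed Peltier temperature shifts, linear conversion of fluorescence (or
    fluorescence-ratio) changes into temperature shifts, extrapolation to
    absolute mitochondrial temperature, rewarming kinetics, drug-background
    quality control for cell-free blanks, autofluorescence-corrected recovery
    accounting for sub-mitochondrial fractionation, replicate statistics
    (one-way ANOVA with Tukey HSD, Student's t), and a seeded forward
    simulator of cuvette thermal dynamics and probe fluorescence used to
    validate every stage by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
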