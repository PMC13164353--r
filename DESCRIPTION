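Package: acepep
Title: Discovery Pipeline for ACE Inhibitory Peptides from Protein Hydrolysates
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dry-lab pipeline for mining angiotensin I-converting enzyme
    (ACE) inhibitory peptides from food proteins, built around the royal
    jelly (major royal jelly protein) use case. Implements in silico
    proteolysis metrics (frequency of occurrence of bioactive fragments,
    theoretical degree of hydrolysis, frequency of release under named
    protease specificities), Box-Behnken response-surface optimisation of
    hydrolysis conditions with full ANOVA diagnostics, composite
    candidate-peptide scoring from mass-spectrometric abundance, de novo
    confidence and docking binding energy, and enzyme-inhibition kinetics
    (Lineweaver-Burk fits, inhibition-mode classification, Ki from secondary
    plots, four-parameter logistic IC50). A synthetic-data module generates
    every pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    minpack.lm,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
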