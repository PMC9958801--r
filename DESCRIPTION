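Package: biofet2d
Title: Compact Modeling of Two-Dimensional Electrolyte-Gated Field-Effect Biosensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Self-consistent compact model of electrolyte-insulator-semiconductor
    (EIS) field-effect biosensors built on two-dimensional semiconductor channels.
    Couples amphoteric site-binding charge on the barrier oxide, a Stern layer,
    the Donnan potential of an ion-permeable membrane of charged macromolecules,
    and the diffuse electrolyte layer into a scalar charge-neutrality solve;
    combines the resulting electrolyte potential drop with two-valley
    Fermi-Dirac sheet-charge statistics and a closed-form drift-diffusion drain
    current for double-gated devices. Provides transfer and output sweeps,
    pH/ionic-strength/analyte-titration studies, Langmuir receptor-target
    binding, threshold-voltage extraction, and sensing figures of merit
    (threshold shift and relative current sensitivity), with tidy tabular
    results and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
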