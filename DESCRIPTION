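Package: nirferm
Title: NIR-Based Monitoring and Closed-Loop Control of Lactic Fermentations
Version: 0.1.0
Authors@R: person("nirferm", "developers", role = c("aut", "cre"),
    email = "nirferm@example.org")
Description: Simulates homolactic and heterolactic batch, fed-batch and
    continuous fermentations (Monod growth with product inhibition,
    Luedeking-Piret production), generates synthetic near-infrared
    spectra for a 19-filter on-line analyzer and a full-spectrum
    transflectance immersion probe (including bubble-induced baseline
    artifacts), and implements the multivariate calibration mathematics
    used for NIR bioprocess monitoring: Norris gap-segment second
    derivative, PCA/Mahalanobis sample screening, multiple linear
    regression, NIPALS PLS1 with PRESS-based factor selection, SEC/SEP/
    RMSEP statistics, calibration transfer across organisms, and five
    NIR-feedback fermentation control strategies (repeated batch,
    repeated fed-batch, turbidostat, chemostat, and repeated batch with
    microfiltration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
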