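Package: egm
Title: Expanded Growth Model for Crop Biomass and Nutrient Accumulation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analytical model of crop biomass accumulation with calendar time
    and of the coupled uptake of mineral nutrients (N, P, K). Biomass is driven
    by a dimensionless growth quantifier built from the error function of a
    Gaussian seasonal solar-energy distribution, a partition coefficient
    between light-gathering and structural tissue, and an aging shift; nutrient
    uptake follows a hyperbolic phase relation with biomass. Provides
    calibration of the yield factor and of per-element phase parameters by
    linearized least squares, closed-form simulation of season-long
    trajectories, a synthetic field-sampling generator with parameter-recovery
    tools, and the corn field-study dataset used for the worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: graphics, stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
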