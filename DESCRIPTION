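Package: lumir
Title: Surface-Hopping Photoisomerization and Lumi-R Intermediate Analysis
    for Bacteriophytochromes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale model of the photoactivation of the Deinococcus
    radiodurans bacteriophytochrome. Provides a reduced-dimensional two-state
    diabatic model of biliverdin D-ring photoisomerization with an engineered
    conical-intersection seam, ground-state thermal sampling, a fewest-switches
    surface-hopping engine with local-diabatization electronic propagation and
    energy-based decoherence, and ensemble statistics (excited-state lifetimes,
    quantum yield, mechanism classification, barrier-lifetime scans). Also
    includes a synthetic generator for chromophore-binding-pocket feature
    trajectories of the early and late Lumi-R intermediates, the corresponding
    analysis pipeline (distance distributions, hydrogen-bond and salt-bridge
    contact probabilities, PCA plus hierarchical clustering, censored
    exponential relaxation kinetics), and a surrogate infrared difference
    spectrum calculator for the carbonyl-stretch region.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    survival
Config/testthat/edition: 3
NeedsCompilation: yes
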