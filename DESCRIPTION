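Package: tabletrom
Title: Coupling Tableting Reduced-Order Models to Dry-Granulation Attributes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Reduced-order models of rotary tableting (Kawakita-type compaction
    force, elastic recovery, out-of-die density, Leuenberger tensile strength,
    and a packing-fraction weight model) coupled to upstream dry-granulation
    attributes (ribbon relative density and a bimodal Weibull granule size
    distribution) through normalized bivariate rational-function surfaces.
    Provides a constrained library of rational-surface variants, AIC-based
    automated model selection, multi-stage constrained global parameter
    estimation, Monte Carlo propagation of tablet-weight variability to
    downstream quality attributes, and a synthetic tableting-campaign
    generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lhs,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
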