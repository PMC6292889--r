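Package: sharktrend
Title: Long-Term Catch-Per-Unit-Effort Trends for Shark Control Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction and hierarchical Bayesian analysis of long-term
    shark catch-per-unit-effort (CPUE) from beach-protection (shark control)
    programs. Provides a synthetic program generator with staggered beach
    installations and two gear types, financial-year catch-record cleaning
    (plausibility filters on total length, proportional reallocation of
    unknown gear), negative-binomial mixed models with an order-2 random-walk
    latent temporal trend and penalized-complexity priors fitted by an
    in-package adaptive Metropolis-within-Gibbs sampler, WAIC model
    comparison, annual zero-catch probabilities, serial-depletion analysis of
    initial CPUE at newly installed beaches via a Poisson mixed model, and
    linear and binomial mixed models for body-size and size-at-maturity
    trends.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    lme4,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    ggplot2
Config/testthat/edition: 3
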