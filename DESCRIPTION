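Package: mwpffc
Title: Modified Weibull Lifetime Inference under Progressive First-Failure Censoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Classical and Bayesian inference for the three-parameter modified
    Weibull lifetime distribution when the data arise from a progressive
    first-failure censoring design. Provides the distribution kernel
    (density, distribution, quantile, hazard and reversed-hazard functions),
    generation of progressively first-failure censored samples by the
    Balakrishnan-Sandhu algorithm, maximum likelihood fitting with
    observed-information Wald intervals and delta-method intervals for the
    survival, hazard and reversed-hazard functions, Bayes estimation under
    squared-error and general-entropy loss via Lindley's approximation and a
    Metropolis-within-Gibbs sampler with percentile credible intervals, a
    Monte-Carlo study engine for comparing censoring schemes, and a worked
    application to a classical kidney-graft survival data set including a
    Kolmogorov-Smirnov goodness-of-fit test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils, graphics, tools, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
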