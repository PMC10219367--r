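Package: wmtransfer
Title: Working-Memory to Long-Term-Memory Transfer: Task Designs, Observer
    Simulation, and Capacity Estimators
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how visual working memory (WM) constrains
    long-term memory (LTM) for objects and object-color bindings. Generates
    single-probe change-detection task designs (WM trials at set sizes 2-4
    with five probe conditions, and a delayed LTM recognition test), simulates
    trial-level three-alternative responses from an explicit
    multinomial-processing-tree observer model, and computes the standard
    measurement battery: guessing-corrected item-memory proportions p(WM) and
    p(LTM), Cowan's k capacity, the LTM/WM transfer ratio, contingent
    binding-error rates with eligibility filtering, and same-color guess-bias
    rates. Includes BIC-approximate Bayes factors for age and set-size
    effects, a default-prior correlation Bayes factor, an end-to-end
    pipeline, and a parameter-recovery experiment validating the estimators
    against the generative model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
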