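Package: aaades
Title: Discrete Event Simulation of Abdominal Aortic Aneurysm Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Individual-level discrete event simulation for evaluating the
    cost-effectiveness of abdominal aortic aneurysm (AAA) screening and
    surveillance policies.  Matched invited/non-invited twin pairs share
    latent attributes (common random numbers); aortic size follows a joint
    continuous-time growth and rupture model; surveillance policies are
    declarative partitions of the diameter axis, so arbitrary interval and
    threshold configurations can be evaluated.  Costs, life-years and
    quality-adjusted life-years are accrued at exact event times with
    continuous-time discounting.  Includes oversampling of aneurysmal
    individuals with reweighting, probabilistic sensitivity analysis with
    ICER, INMB and CEAC reporting, trial-style validation tables, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    parallel,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
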