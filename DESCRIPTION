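Package: lynchcea
Title: Cost-Effectiveness of Gynecologic Cancer Prevention in Lynch Syndrome
Version: 0.1.0
Authors@R:
    person("Model", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Markov state-transition cohort model of Lynch-syndrome-associated
    endometrial and ovarian cancer for carriers of pathogenic MLH1, MSH2, MSH6
    and PMS2 variants.  Calibrates annual cancer-onset probabilities to
    gene-specific cumulative-incidence targets, simulates surveillance and
    risk-reducing surgery strategies (including a two-stage hysterectomy with
    bilateral salpingectomy followed by delayed oophorectomy), and performs a
    full cost-effectiveness analysis: discounted quality-adjusted life-years
    and lifetime costs, efficiency frontier with dominance and incremental
    cost-effectiveness ratios, one-way and threshold sensitivity analyses, and
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
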