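Package: waspnest
Title: Multi-Scale Stochastic Dynamics of Dominance and Caste in Paper Wasp Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how reproductive division of labour self-organizes
    in small paper wasp (Polistes) societies. Implements a minimal biophysical
    model coupling per-insect queen-gene product dynamics to colony-level
    dominance interactions: exact event-driven (Gillespie) simulation of the
    reduced and full master equations, the deterministic mean-field transport
    equation for the colony composition with phase portraits, separatrix and
    saddle-node bifurcation analysis, closed-form queen-persistence-time
    statistics under gene-expression noise with Monte-Carlo verification,
    estimation of interaction rate, dominance-error rate and interaction
    asymmetry from behavioural event logs, the behavioural, imaging and
    expression observables used to characterize colony state (interaction,
    fight and dominance indices, frame-differencing activity, ovary maturity,
    queen-profile correlation, expression variability versus DNA methylation),
    and seeded synthetic-data generators for every input so each analysis step
    can be exercised as a parameter-recovery problem.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    jsonlite
Config/testthat/edition: 3
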