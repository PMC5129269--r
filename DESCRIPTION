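Package: wfcsim
Title: System-Dynamics Simulation of Work-Family Conflict in Construction
    Employees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic stock-and-flow simulation engine (piecewise-linear
    lookup tables, first-order exponential delays, fixed-step Euler
    integration, dependency ordering and feedback-loop enumeration) together
    with a complete bi-directional model of work-family conflict for
    construction-industry employees over a 36-month project life cycle. The
    model couples work interference with family conflict (WIFC) and family
    interference with work conflict (FIWC) through job and family
    satisfaction, involvement, pressure and performance, and supports
    moderator scenarios for work flexibility, family support and
    organizational support, with trend classification and scenario-comparison
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
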