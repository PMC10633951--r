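Package: lacodose
Title: Monte Carlo Dose-Finding for Lacosamide During Continuous Renal
    Replacement Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates lacosamide exposure in virtual critically ill adults
    receiving continuous renal replacement therapy (CRRT) and evaluates
    intravenous dosing regimens by probability of target attainment (PTA).
    Virtual patients are drawn from truncated normal parameter
    distributions; extracorporeal clearance is computed from the CRRT
    prescription (CVVHD saturation-coefficient or pre-dilution CVVH
    sieving-coefficient models); 72-hour concentration-time profiles follow
    a closed-form one-compartment intermittent-bolus superposition model.
    Patients are classified against trough and 24-hour AUC therapeutic
    ranges, optimal regimens are selected by a lowest-dose rule, and the
    effect of body weight on target attainment is quantified with 2x2 risk
    ratios and log-binomial regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
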