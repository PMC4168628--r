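Package: heatdose
Title: Heat-Dose Kinetics and Discard Survival for Temperature-Time
    Indicators on Oxytocin Devices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how long heat-sensitive pharmaceutical
    devices monitored by cumulative temperature-time indicators (TTIs)
    remain usable outside the cold chain. Implements an Arrhenius
    lifetime model of the indicator, cumulative heat-dose integration
    over logged temperature series, mean kinetic temperature summaries,
    Kaplan-Meier and Weibull proportional-hazards analysis of
    daily-observed discard times with cluster-robust (Huber-White)
    standard errors, a simulation-based sample-size procedure for
    estimating a Weibull median to a stated precision, and a Monte
    Carlo resupply/wastage simulator for community distribution
    programmes. Ships a synthetic-data generator emulating a two-season
    field storage study in rural Ghana so every stage is testable
    without the original field records.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    survival,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
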