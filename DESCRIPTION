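Package: biogasbench
Title: Mechanistic and Machine-Learning Prediction of Full-Scale Biogas Production
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates daily biogas and methane production of a full-scale
    agricultural co-digestion plant with a simplified anaerobic-digestion
    model (first-order hydrolysis of carbohydrates, proteins and lipids in a
    CSTR with Buswell gas stoichiometry, optional Monod methanogenesis
    extension), calibrates hydrolysis rate constants against observed biogas
    by bound-constrained RMSE minimisation, and benchmarks the mechanistic
    model against random-forest and LSTM regressors built from daily feeding
    records. Includes feedstock fractionation from proximate (Weender)
    analysis, Nash-Sutcliffe efficiency scoring at daily and weekly
    resolution, exact and sampling-based Shapley feature attribution, a
    synthetic plant-campaign generator for end-to-end testing, and wall-clock
    and resident-memory profiling of training and inference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    parallel,
    deSolve,
    minpack.lm,
    ranger,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
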