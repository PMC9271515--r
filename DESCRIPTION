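Package: ctaccess
Title: Distance-Based Accessibility of Cancer Clinical Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes a gravity-model, distance-based accessibility index
    (dAI) of cancer clinical trials on gridded population data: trials at
    the nearest site attenuated by inverse square-root great-circle
    distance and by the logarithm of the expected local patient count.
    Provides national aggregation weighted on log patient volume, a
    travel-cost variant (tAI), cross-country normalization, Gini/Lorenz
    inequality profiling globally and within countries, time-trend
    statistics (relative increments, AUC comparison, Mann-Kendall test,
    Pearson correlation, period means), a greedy algorithm that places new
    trial sites to maximize the national index, scenario simulation, and a
    synthetic-country generator so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
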