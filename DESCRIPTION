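Package: nutrioverlap
Title: Overlap of Nutrient-Profile (HFSS) and Nova Ultra-Processed Food
    Classifications in Diet Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores foods with the UK Nutrient Profiling Model (2004/05 and
    provisional 2018 variants) to flag products high in fat, salt or sugar
    (HFSS), assigns Nova food-processing groups through a hierarchical rule
    table with override predicates, and quantifies the overlap of the two
    classifications in diet-diary data. Overlap is partitioned into
    HFSS-only, UPF-only, both and neither on three bases (food count,
    energy and food weight), at food level and as survey-weighted
    person-level means with two-sided confidence intervals, including
    age-band and sex subgroup tables and top-contributor breakdowns by
    main food group. A seeded synthetic diet-diary generator with known
    ground truth supports end-to-end testing without survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
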