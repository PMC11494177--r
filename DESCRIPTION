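Package: heatmort
Title: Multi-Scale Heat-Related Mortality Modelling and Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates daily, district-level, age- and sex-stratified heat-related
    excess mortality from temperature. A trainable exposure-response model (a sum of
    exponential terms over a lag window of daily mean temperatures) multiplies a
    log-linear baseline mortality rate and daily population to give expected deaths,
    and is calibrated by Poisson likelihood against coarsely aggregated mortality
    reporting streams (daily by state and sex; weekly by state, sex and broad age;
    weekly national by sex and fine age). An attention-weighted spatial interpolator
    maps station or climate-model grid temperatures to district level and doubles as
    a statistical downscaler. Heat-related excess deaths are attributed through a
    capped-temperature counterfactual, and future burdens are projected under
    climate-scenario temperature ensembles. A synthetic-data generator with known
    ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    lubridate,
    ggplot2,
    generics,
    geosphere,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
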