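Package: hmisdq
Title: Data-Quality Assessment for Routine Health Management Information Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing the quality of routine health management
    information system (HMIS) data as it travels from facility registers and
    tally sheets through monthly report forms and district copies into DHIS2.
    Provides a generative simulator of the five-source facility-to-DHIS2
    "data journey" with explicit, configurable error processes (recording
    misses, tally over-marking, report inflation, transmission losses,
    undocumented corrections, entry errors); tool-availability and
    report-completeness rates with median/IQR summaries and a four-level
    availability categorisation; a rule-based completeness audit of row-level
    register records; and six difference-ratio accuracy indices grouped into
    health-facility, transmission and robust phases with a seven-level match
    categorisation, stratified by year, service area, indicator, facility
    level, ownership and district. Includes colour-coded table export and an
    end-to-end reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
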