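Package: bsetr
Title: Quantifying Repetitive Head Impact Exposure from Annotated Game Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring repetitive head impact (RHI) exposure in
    American-style football from annotated per-game head-impact logs.
    Estimates impact velocity from frame-track coordinates via planar
    homography, assigns brain-tissue maximum principal strain (MPS) through
    exemplar reconstruction lookup tables, converts game-clock stamps to
    real inter-impact time intervals with stop-time correction, scores
    cumulative exposure with the BSE/T (brain strain exposure per time)
    index, and compares player field positions with rank-based and
    contingency-table statistics. Includes a seeded synthetic game-log
    generator emulating position-specific exposure profiles so the full
    pipeline is testable without any game footage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
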