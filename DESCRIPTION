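Package: attnfusion
Title: Redundant Classroom Attention Detection from Facial Expressions and
    Heart-Rate Variability
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts two independent, non-invasive sensor streams recorded
    during lectures -- per-frame facial-expression labels and 1 Hz smartwatch
    heart data (heart rate and beat-to-beat intervals) -- into comparable
    per-second binary Attention Arrays, aggregates them across students,
    and validates one source against the other through a window-size-selecting
    RMSE criterion. Includes time-domain heart-rate-variability features
    (SDNN, SDSD, RMSSD, pNN50), an activation-level classifier over
    active/passive moods, a 5-minute attention-counter filter producing the
    classroom Attention Behavior, a reaction-time self-report analyzer, and a
    seeded regime-switching simulator that generates complete synthetic
    lecture sessions with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
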