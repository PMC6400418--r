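Package: landmem
Title: Ideal-Observer Modelling of Landmark Effects in Spatial Working Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how a task-irrelevant visual landmark improves
    recall of remembered locations on a circle. Implements a cue-integration
    ideal observer in which an egocentric estimate of distance-independent
    precision is combined with an allocentric estimate whose precision decays
    exponentially with target-landmark distance, contaminated by a uniform
    lapse component. Provides generators for the four landmark experiment
    designs, forward simulation of observer responses, constrained
    maximum-likelihood fitting with declarative parameter tying across
    conditions and set sizes, AICc model comparison (including a reduced
    no-allocentric variant and an egocentric-cost variant), and the binned
    circular summary statistics (median signed deviation and median absolute
    deviation versus landmark distance) used to visualise landmark effects.
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
    optparse,
    withr
Config/testthat/edition: 3
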