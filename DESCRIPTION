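Package: chasescan
Title: Gaze-Event Decomposition and Template Analysis for Chase Detection Displays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how observers find a chasing pair among
    randomly moving agents. Simulates chase displays in which one agent
    pursues another in a heat-seeking manner among distractors, generates
    synthetic binocular eye-tracking recordings of observers who explore and
    pursue the agents, preprocesses raw gaze into a fused signal with
    velocity and acceleration, segments it into fixations, saccades and slow
    or fast smooth eye movements, aggregates these into pursuit and
    exploration episodes, and runs spatiotemporal template analyses around
    gaze events: principal-component movies, kernel-regression average
    templates, rail diagrams with line fitting, support-vector-machine
    classification movies, and a chase-centered ideal-observer analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools, e1071, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
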