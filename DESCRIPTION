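Package: trialkit
Title: Headless Session-Block-Trial Experiment Engine with Cascading
    Settings and Deferred Data Writes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An engine-agnostic core for running human-behavior experiments
    organized in the session-block-trial model. Provides automatic trial and
    block numbering with lifecycle events, hierarchical settings that cascade
    from trial to block to session to a JSON profile, per-trial continuous
    tracking of time-varying quantities (e.g., head position at 90 Hz),
    behavioral and continuous CSV output in an experiment > participant >
    session directory layout, a durable deferred write queue with post-write
    hooks, and a participant demographics registry. Includes a synthetic
    replication of the classic swinging-room postural-sway paradigm (path
    length of head movement under a sinusoidally oscillating visual surround)
    and a scripted two-block number-doubling demonstration, plus a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
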