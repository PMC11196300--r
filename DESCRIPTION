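Package: egolens
Title: Personal Social Network and Experience-Sampling Feedback Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ingesting two-wave personal social network (PSN) data
    together with experience-sampling (ESM) momentary assessments and
    event-contingent social-interaction diaries, reconciling network membership
    and role changes across waves, computing the descriptive statistics used in
    personalised social-context feedback (role composition, interaction counts
    and quality summaries with confidence intervals, affect timelines,
    perception-behaviour discrepancies, network structure, and term
    frequencies), and rendering a self-contained interactive HTML feedback
    report. Includes a fully synthetic cohort simulator with role-structured
    networks, signal-contingent prompt schedules, and affect series coupled to
    interaction quality, so the whole pipeline is testable without participant
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    igraph,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
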