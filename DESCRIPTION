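Package: sleepspikes
Title: Perievent Analysis of Sleep Twitches and Precerebellar Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing extracellular unit activity recorded from
    precerebellar nuclei of sleeping infant rodents together with
    electromyographic (EMG) signals. Provides EMG-based behavioural-state
    scoring (active wake, behavioural quiescence, active sleep) and myoclonic
    twitch detection; perievent time histograms with interval-jitter surrogate
    resampling and simultaneous confidence bands that control the family-wise
    error rate; latency-window classification of corollary-discharge, motor
    and reafferent responses; state-dependence classification of units from
    per-bout firing rates; and a two-group comparison battery (chi-squared
    tests on unit proportions, Mann-Whitney U tests with outlier exclusion,
    pooled and normalized histograms). A synthetic-session generator with
    ground truth makes every stage testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
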