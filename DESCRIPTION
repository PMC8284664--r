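Package: sbltransfer
Title: Sequential Bayesian Learning and Transfer Across Shared Task Subspaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying transfer learning in
    multitask neural value networks trained by sequential Bayesian (Laplace
    approximate) learning, also known as elastic weight consolidation. Provides
    the probabilistic category-learning environment (a two-cue weather/coin
    prediction task with log-quadratic and log-linear stimulus-reward maps),
    a multitask feedforward value network with a shared first hidden layer and
    per-task output subnetworks, MAP estimation by gradient ascent with bounded
    line search and multistart, diagonal Laplace posterior-precision updates,
    simulation protocols over tasks and over trial blocks, and the transfer
    statistics (Pearson correlations, Fisher r-to-z contrasts, t tests) used
    to summarise positive and negative transfer between tasks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
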