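Package: mazelang
Title: Emergent Communication Between Teacher and Student Agents in Grid-World Mazes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A teacher-student framework for studying emergent communication.
    Deep-Q teacher agents each solve one grid-world maze task; a sparse
    autoencoder compresses their state-action value tables into
    low-dimensional real-valued messages, optionally shaped by feedback from
    a student agent whose policy is evaluated analytically through an
    absorbing Markov chain; a student learns to solve tasks from messages
    alone.  Includes representation analyses (group-variance decomposition
    with F tests, topographic similarity, binned entropy of principal-
    component projections), evaluation against misinformed and random-walker
    baselines, and a close-the-loop protocol in which student-generated task
    information is re-encoded through a frozen language.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0), igraph, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
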