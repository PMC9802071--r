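Package: semexplore
Title: Semantic Networks and Reinforcement-Learning Models of Word Association Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing word association data collected under
    instructed search strategies (ordinary, creative, random). Builds
    group-level semantic networks from association overlap with
    Triangulated Maximally Filtered Graph (TMFG) sparsification and
    topological quantifiers (clustering, path length, modularity,
    small-worldness), runs edge-threshold percolation with robustness
    integrals, scores responses by word-embedding semantic distance and
    category switching, and fits the Semantic Explorer (SemExp) softmax
    choice model with a single inverse-temperature parameter by gradient
    descent. Includes a synthetic-data generator with known ground truth
    (embedding spaces, responses, rater scores), permutation-based paired
    inference, and intraclass correlation for rater agreement.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
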