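Package: pphr
Title: Patient-Physician Hybrid Recommendation for Web-Based Medical Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A top-K physician recommender for web-based medical consultation
    platforms. Given a corpus of historical consultation records and a new
    free-text medical question, the patient-physician hybrid recommendation
    (PPHR) engine retrieves semantically similar historical questions,
    expands the candidate physician pool through TF-IDF keyword profiles and
    physician-physician similarity, and re-ranks candidates by their response
    rate. Includes per-physician response metrics with percentile
    winsorization, pluggable deterministic text-embedding backends, a full
    evaluation suite (hit ratio, precision/recall/F1 at K, high-quality
    service proportion, K sweeps, rating comparisons), a synthetic-corpus
    generator with known ground truth, and a command-line interface chaining
    all stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    stringi,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
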