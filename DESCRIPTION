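Package: ohcread
Title: Readability and Lexical Diversity Analysis of Online Health Community Posts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring written-communication quality in online
    health communities. Computes per-post readability grade levels
    (Flesch-Kincaid, SMOG, Gunning Fog, Linsear Write) and lexical
    diversity from scratch (sentence segmentation, tokenization,
    heuristic syllable counting), aggregates them with member-equalized
    two-step means and per-community min-max normalization, compares
    communities with pairwise t-tests, Hommel-adjusted p-values, Cohen's
    d effect sizes and 95% confidence intervals, and estimates per-member
    longitudinal trends by least-squares regression of post scores on the
    interaction sequence. A synthetic corpus generator with pseudo-word
    vocabularies of known syllable structure provides ground truth for
    validating every stage without external data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
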