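Package: rediaDOL
Title: Division-of-Labor Pattern Assessment for Trematode Redia Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess morphological and behavioural patterns associated
    with reproductive division of labor in clonal colonies of trematode rediae
    sampled from snail hosts. Provides morphometric estimation (cylindrical body
    volume, spherical pharynx volume, relative pharynx size, standard linear
    size), a two-branch size-caste designation procedure (histogram-trough
    bimodality detection with a quartile fallback), a battery of nonparametric
    per-colony pattern tests with Table-style result codes, Tukey-fence
    detection of large-pharynx rediae, COI percent-identity species clustering
    with a built-in global aligner, tabular reporting, and a synthetic colony
    generator with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
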