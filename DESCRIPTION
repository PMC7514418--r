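Package: cpdna
Title: Reference-Free Lossless DNA Compression by Competitive Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lossless, reference-free compression of DNA sequences (A, C, G, T)
    using a competitive prediction between two classes of adaptive models: a
    weighted set of finite-context models, optionally extended with
    substitution-tolerant context models and an inverted-repeat sub-program,
    and a weighted set of stochastic repeat (copy) models spawned from a k-mer
    position index. Class mixtures use exponential-forgetting weight updates,
    a binary competitive-prediction context model selects the class coded at
    each base, and an integer-quantized range coder produces a deterministic,
    platform-independent bitstream with a self-describing header that makes
    decompression exactly symmetric. Includes fifteen resource presets, a
    deterministic synthetic-DNA fixture generator (random, tandem, dispersed
    and inverted repeats, with substitution noise), per-base instrumentation
    for model diagnostics, and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
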