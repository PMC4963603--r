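Package: sdpcnn
Title: Protein-Protein Interaction Extraction with a Shortest Dependency
    Path CNN
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts candidate protein-protein interactions from
    dependency-parsed biomedical sentences. The shortest dependency path
    between two blinded protein mentions is serialized as an interleaved
    word/relation token sequence, embedded (pretrained word2vec vectors
    or random initialization), and classified by a small convolutional
    network with max-over-time pooling, one hidden layer and a softmax,
    trained by per-example Adadelta. Includes CoNLL-style parse and
    word2vec readers, stratified k-fold cross-validation, learning
    curves, key-word attribution, and a synthetic corpus generator with
    a planted interaction-verb signal.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
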