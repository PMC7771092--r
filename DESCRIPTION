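Package: cnormr
Title: Few-Shot Entity Normalization with Hierarchy-Encoded Concept Vectors
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Normalizes textual entity mentions to ontology concepts by
    training shallow neural networks (a single-layer feedforward network, a
    shallow convolutional network, and their end-to-end averaging ensemble,
    C-Norm) to project word-embedding representations of mentions onto
    concept vectors that encode the ontology is_a hierarchy with a decay
    factor. Supports weak supervision from ontology concept labels, OBO and
    BioNLP-ST standoff input/output, word2vec embedding loading, cosine
    nearest-neighbour decoding with a sieve combiner, and evaluation with
    strict exact-match and Wang semantic-similarity scores. Includes a
    synthetic fixture generator emulating the few-shot/zero-shot structure
    of habitat- and phenotype-normalization corpora.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
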