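Package: litmine
Title: Full-Text Literature Mining, Search, and Curation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A literature mining engine for biomedical full text. Converts
    JATS/NXML or plain-text articles into immutable standoff-annotated
    documents, compiles OBO ontologies and custom term lists into a shallow
    category hierarchy with per-category lexica, marks up category term
    occurrences by token-sequence dictionary matching, builds an inverted
    index over keywords and category annotations, and answers combined
    boolean keyword/category queries at sentence or document scope with
    normalized tf-idf ranking. Also provides configurable curation-form
    schemas whose span-linked records export as JSON or parameterized URIs,
    and deterministic synthetic fixture generators (toy ontologies and NXML
    corpora with planted terms) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
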