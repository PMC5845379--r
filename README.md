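# litmine

Full-text literature mining, search, and curation for biomedical text.

Biocurators extract structured knowledge — gene functions, alleles,
phenotypes, interactions — from a literature that grows by more than a
million articles a year. Plain keyword search is a blunt instrument for
this: what curators need is to search the *full text* of articles for
combinations of keywords and **categories** (semantically related groups
of terms derived from ontologies such as GO, or from curator-maintained
word lists), restricted to the sentence or document level, and then to
turn the matching passages into database annotations without retyping
anything. litmine is an engine for exactly that workflow: it is a
library plus a command-line tool for people building curation pipelines
and literature-search services, and for anyone who wants a fully
deterministic, testable concept-search engine over their own corpus.

## What it does

* **Standoff document model** — each article becomes an immutable
  full-text string (the SofA) plus layered standoff annotations
  (`token`, `sentence`, `paragraph`, `section`, `image`, `lexical`,
  `manual`, `computational`), stored losslessly as one JSON file per
  article under a manifest. Offsets are 0-based, half-open, in code
  points.
* **Ingestion** — JATS/NXML (PubMed Central style) or plain text;
  tokenizer with biomedical-friendly internal separators (`zyg-1` is
  one token), sentence splitter with an abbreviation exception list
  ("C. elegans", "Fig. 3" never split), figure/table captions included
  in the searchable text.
* **Categories** — OBO ontologies compiled into a shallow forest of
  maximum depth 4; terms deeper than the cut fold their names and
  synonyms into their depth-4 ancestor, so nothing becomes
  unsearchable. Custom word lists compile through the same pipeline.
* **Dictionary annotation** — a token-sequence trie marks every
  occurrence of every category surface form (all matches, not just the
  longest; case policy per form; `DNA binding` matches `DNA-binding`;
  no match crosses a sentence boundary). Regex rules over
  title/journal/subjects assign sub-corpus labels such as "Genetics"
  (pattern `[Gg]enet`).
* **Search** — an inverted index over keywords and category
  annotations answers boolean queries (`AND`/`OR`/`NOT`, quoted
  phrases, parentheses) combined with conjunctive category clauses
  (optionally expanded to child terms), at sentence or document scope,
  with author/journal/year/accession/section/sub-corpus filters and
  keyword exclusion. Hits are ranked by a pinned tf-idf weight

  &nbsp;&nbsp;&nbsp;&nbsp;*w*(tf, df) = (1 + ln tf) · ln(1 + N/(1 + df))

  summed over positive clauses and normalized so the best document
  scores 1.0; results sort by score or by year.
* **Curation** — configurable form schemas (grid-placed fields with
  autocomplete sources, validators, and prepopulation from
  bibliography or from the category terms inside highlighted spans);
  records carry non-contiguous evidence spans and export as JSON or as
  an RFC 3986 parameterized URI, with an external system's identity
  token passed through verbatim.
* **Fixtures** — deterministic generators for toy OBO ontologies and
  NXML corpora with terms planted at known offsets, so the whole
  pipeline is validated against exact ground truth and brute-force
  oracles, offline.

## Worked example

```r
library(litmine)

# two categories: a word list and a small gene list
enz   <- category_from_termlist("Enzymatic Activity",
           c("kinase activity\tphosphorylation activity",
             "protease activity"))
genes <- category_from_termlist("Worm Genes", c("ZYG-1", "SAS-6"))
forest <- merge_forests(enz, genes)
tree   <- build_lexicon_tree(forest)

d1 <- convert_article(
  paste0("ZYG-1 phosphorylates SAS-6 in embryos. ",
         "The kinase activity of ZYG-1 is required for centriole duplication."),
  bibliography("12345", title = "Phosphorylation of SAS-6 by ZYG-1",
               journal = "Developmental Cell", year = 2014))
d2 <- convert_article(
  "Transcription factors show DNA-binding activity. Enhancers recruit them.",
  bibliography("67890", title = "Gene regulation in development",
               journal = "Genome Medicine", year = 2017))
d1 <- annotate_document(d1, tree)
d2 <- annotate_document(d2, tree)
idx <- build_index(list(d1, d2))

# sentences that contain the phrase "kinase activity" AND a gene mention
q <- lit_query('"kinase activity"',
               categories = list(list(id = genes$roots, children = FALSE)),
               scope = "sentence")
res <- search_index(idx, q, forest)
print(res)
#> 1 documents, 1 matching sentences (sentence scope, sorted by score)
#>  Accession                             Title            Journal Year Type Score
#>      12345 Phosphorylation of SAS-6 by ZYG-1 Developmental Cell 2014          1
```

One document qualifies, with a normalized document score of 1.0 (the
top-ranked document always scores 1 after normalization). The single
matching sentence is the one in which the phrase and a gene mention
co-occur — "The kinase activity of ZYG-1 is required for centriole
duplication." (raw sentence score 1.3863: two positive clauses, each
with tf = 1 and df = 1 in a two-document index, each contributing
ln 2 ≈ 0.6931). The first sentence of `d1` mentions both genes but not
the phrase, so it is not returned; `d2` contains neither clause.

From a hit you can highlight spans and export a curation record:

```r
sent <- doc_layer(d1, "sentence")[2, ]
schema <- form_schema("go_mf",
  list(form_field("term", row = 0, col = 0,
                  prepopulate = "span_terms:any")),
  target_url = "https://curation.example/form",
  transport = "parameterized_uri")
vals <- prepopulate(schema, d1, sent)
rec  <- curation_record(d1, sent, field_values = vals,
                        curator = "kv", token = "abc123")
export_record(schema, rec, d1)$body
#> "https://curation.example/form?form_name=go_mf&accession=12345&..."
```

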