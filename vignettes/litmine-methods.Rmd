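---
title: "litmine: models and design of the literature-mining engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{litmine: models and design of the literature-mining engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litmine)
```

litmine is a back end for full-text literature search and biocuration:
it turns articles into annotated documents, marks up occurrences of
ontology-derived concept classes ("categories"), indexes everything, and
answers combined keyword/category queries whose hits can be curated and
exported to external databases. This vignette explains the underlying
models, the parameters that matter, and the design decisions taken where
the design space was genuinely open.

## The standoff document model

Every article is reduced to a single immutable string, the *subject of
analysis* (SofA), and all derived information is stored as *standoff
annotations*: typed spans `(layer, begin, end, attributes)` that
reference the SofA by offset and never modify it. Offsets are 0-based
and half-open, counted in Unicode code points; this convention is fixed
once and used by every module, including the exported curation payloads.

Layers form a closed set: `token`, `sentence`, `paragraph`, `section`,
`image` (figure/table captions with their graphic references), `lexical`
(dictionary matches), `manual` (curation marks) and `computational` (a
first-class layer reserved for external NLP annotators; litmine ships no
machine-learning annotator, but the layer exists so third-party tools
can attach their output and have it indexed like any other annotation).

Structural invariants are enforced at validation time, never silently
repaired: sentence and token layers are non-overlapping, every token
lies in exactly one sentence, and every lexical annotation coincides
with whole tokens. Persistence is one canonical JSON document per
article under a manifest — a deliberately boring format that is
lossless, diffable and dependency-free, in place of a database. The
save/load round trip is the identity on valid documents and is
property-tested with randomized annotation sets.

## Ingestion

The converter accepts JATS/NXML (the PubMed Central tagging style) and
plain text with sidecar metadata. The SofA is assembled as title,
abstract, body paragraphs and figure/table captions, in document order,
separated by blank lines. Captions are deliberately part of the
searchable SofA: a common curation pattern restricts matching sentences
to those referencing a table or figure, which only works if caption
text is findable. Reference-section text, when present as a body
section, keeps its section label so it can be filtered later.

Tokens are maximal runs of letters and digits in which `-`, `.`, `/`,
`_` and `'` are token-internal iff flanked on both sides by a letter or
digit — so `zyg-1` and `e.g` are single tokens while `end. Next` splits
cleanly. Sentence boundaries occur after `.`, `!` or `?` followed by
whitespace and an uppercase letter or digit, except after entries of a
configurable abbreviation list (`Fig.`, `Figs.`, `et al.`, `e.g.`,
`i.e.`, `vs.`, `ca.`) and after single-capital genus abbreviations, so
"C. elegans" never splits. Sentence spans are the whitespace-trimmed
segments between boundaries: a sentence carries its terminal
punctuation but not inter-sentence whitespace. The partition property
that matters downstream — every token lies in exactly one sentence —
holds by construction and is asserted in the tests.

## Categories: ontologies folded to a shallow forest

Categories are compiled from OBO flat files (term names plus synonyms
of every scope, `is_a` relations, obsolete terms dropped) or from
custom word lists. For browsing and child-term expansion the ontology
is cut to a forest of maximum depth 4. Terms deeper than the cut are
*folded*, not discarded: their names and synonyms join the lexicon of
their nearest ancestor at depth 4. Folding was chosen over truncation
because deep terms must remain searchable; it also makes "search child
terms" unambiguous — expanding a node over the browsable forest is then
the same as expanding over the full ontology. Terms with several
`is_a` parents attach under the parent reached first in a
breadth-first traversal ordered by term id, a deterministic tie-break
chosen purely for reproducibility.

Word lists enter the same machinery: each list is representable as an
OBO stanza set (a root stanza plus one stanza per line, `is_a` the
root), and compiling that representation at depth 1 folds every line
term into the single root node. The only asymmetry is that the OBO
route's lexicon also contains the category name itself, since a root
term's name is always part of its own lexicon; `category_from_termlist()`
keeps the narrower reading (terms and synonyms only).

Each surface form carries a case policy: matching is case-sensitive iff
the form contains a digit or an uppercase letter after its first
character. Thus `ZYG-1`, `DnaK` and `zyg-1` match exactly, while
`kinase` also matches `Kinase` at a sentence start. The policy is a
heuristic tuned to biological naming (gene symbols and alleles are
case-bearing; ordinary nouns are not) and is recorded per form at
compilation time.

## Dictionary matching

The lexical annotator compiles all surface forms into a trie keyed by
token sequences (lowercased; hyphenated tokens split at their hyphens
into match units) and scans each sentence's token stream. The policies,
each of which is pinned by tests against a brute-force all-window
oracle:

* **All matches, not longest-only.** At every token position all forms
  starting there are reported, so `kinase` and `kinase activity` both
  annotate the same stretch. Search semantics require this: a query for
  the shorter category must find sentences that happen to contain the
  longer form.
* **Token alignment.** Matches start at a token begin and end at a
  token end; `gene` never matches inside `Generation`.
* **Separator tolerance.** Between matched units, whitespace or a
  single hyphen is accepted, so `DNA binding` matches `DNA-binding` and
  vice versa. This reflects common biomedical orthography and can be
  disabled (`hyphen_split = FALSE`). A consequence of the strict rule
  is that forms with other internal separators between tokens (for
  example a genus dot, as in "C. elegans embryo") do not match across
  that separator; such forms are rare in practice and are left to exact
  single-token matching.
* **Sentence containment.** No match crosses a sentence boundary.
* **Idempotence.** Annotation replaces the lexical layer, so re-running
  the annotator reproduces the same set.

Sub-corpus labels (e.g. "Genetics") are assigned by regular-expression
rules over title, journal and subject fields — the conventional example
is the pattern `[Gg]enet` — and restrict searches to a labeled subset
of the collection. Rules live in a small JSON config; regex
classification is simple and transparent, though it shares the known
weakness that title/journal/subject keywords do not always classify a
paper correctly.

## Indexing, query language, and scoring

The inverted index records, per document: the lowercased token stream
with sentence ordinals and positions, category annotations with their
sentences, section spans, and the bibliographic filter fields; plus
document-frequency tables for keywords and categories. It is serialized
canonically, so identical inputs give byte-identical index files — a
property the tests assert end to end.

Queries combine a boolean keyword expression (uppercase `AND`, `OR`,
`NOT`; juxtaposition means `AND` and binds tighter than `OR`; quoted
strings are phrases; parentheses group) with a list of category
clauses. Category clauses are *conjoined* — every selected category must
be present in the unit — matching the standard multi-category curation
search ("at least one term from all selected categories"); disjunctive
category semantics are deliberately unsupported. The *scope* decides
the unit that must satisfy the whole query: a sentence or a document.
Phrases always require consecutive tokens within one sentence, at
either scope. Filters (author and journal as case-insensitive
substrings, year or year range, exact accession, sub-corpus label,
section label) restrict the document set before evaluation; excluded
keywords remove any unit containing them at the query's scope.

Scoring uses a pinned tf-idf variant,

$$ w(\mathrm{tf}, \mathrm{df}) = (1 + \ln \mathrm{tf}) \cdot
   \ln\!\left(1 + \frac{N}{1 + \mathrm{df}}\right), $$

summed over the positive clauses of the query (term and phrase leaves
not under a `NOT`, and every category clause; a clause with tf = 0
contributes 0). `df` is always a document frequency; sentence scores
use sentence-level tf with document-level df and N. A phrase's df is
approximated by the df of its rarest member token — an index-compactness
choice that can only affect ranking, never membership. Document scores
are normalized by the highest-scoring returned document, so the top
document scores exactly 1.0. The formula itself is a design choice:
"tf·idf" names a family, and production search libraries have changed
their similarity over versions, so a pinned formula is the only way to
make scoring exactly testable. An independent re-implementation of the
formula in the test suite agrees with the engine to 1e-12.

Two degenerate cases are worth knowing. With `sort = "year"`, unknown
years sort last, ties break by score then document id. And a query
whose only satisfied clauses are negations (e.g. `a OR NOT b` in a
document containing neither term) yields a raw score of 0; such hits
are reported with score 0 (or a uniform 1.0 when no returned document
scores above 0), outside the usual (0, 1] band — typical searches with
at least one positive matched clause always stay inside it.

## Curation forms and export

Form schemas place typed fields (line edit, text area, pulldown,
checkbox) on a grid; each field may carry an autocomplete source, a
validator (value list, category membership, or regex) and a
prepopulation rule (static text, a bibliography field, or the category
terms found inside the highlighted spans, rendered as
`"surface form [term id]"`). Evidence spans may be non-contiguous —
curators collect supporting statements from anywhere in a paper —
and overlapping selections are merged at record creation. Export
refuses records with outstanding diagnostics and produces either a
JSON object or an RFC 3986 percent-encoded parameterized URI; both
decode to identical content, evidence text is sliced byte-for-byte
from the SofA, and an identity token received from the external system
is passed through verbatim so the annotation lands in the right place
there. External autocomplete services are represented as URL templates
behind a pluggable fetch interface; tests use a local stub, and no
network transport is built in. The parameter naming of the URI form
(`evidence.<k>.begin/end/text`, `field.<id>`) is this package's own
documented convention.

## Synthetic fixtures: what they do and do not show

The fixture generators produce toy OBO ontologies (default 30 terms,
depth up to 6 so folding is exercised, 0–2 synonyms per term, some
synonyms carrying digit suffixes so case-sensitive matching is hit) and
NXML corpora (default 20 articles; 1–2 abstract sentences; two body
sections of 1–2 paragraphs with 3–8 sentences each; half the articles
carry a figure caption; 1–5 planted term occurrences per article;
titles drawn from templates that exercise the sub-corpus regexes;
years 1995–2020). All sampling is driven by a single seed and the
output is byte-identical across runs.

Two design rules make the ground truth exact rather than probabilistic:
filler vocabulary and term words come from disjoint alphabets (filler
uses letters a–h; term words start with "q" and continue with n–z), and
all term/synonym words are drawn without replacement, so no planted
form can occur by accident, inside filler, or nested within another
form. Case-mangled decoys of case-sensitive forms are planted that must
*not* be annotated. Some sentences embed "C. elegans" and "see Fig. 3"
patterns so abbreviation handling is exercised with known boundaries.

This is deliberately unlike real text: real articles contain ambiguous
and nested terms, inconsistent casing, markup noise, and prose whose
sentence structure defeats rule-based splitting more often. Passing
fixtures therefore demonstrates the *mechanics* — exact offsets, policy
compliance, determinism, index/search correctness — not linguistic
recall on real literature. The brute-force oracles complement this by
testing the matcher and the search engine on randomized inputs with
overlapping forms and realistic casing, independent of the planted
corpora.

## Validation problem sizes

The shipped tests and the acceptance script run the annotator/oracle
comparison on 100–200 randomized document–lexicon pairs (up to ~30
sentences and ~50 surface forms each), the search/oracle comparison on
a 100-document seeded corpus with 50 randomized queries covering
boolean operators, phrases, category clauses with and without child
expansion, both scopes, filters and exclusions, and the determinism and
round-trip checks on 10–20 document corpora. These sizes were chosen so
the whole validation suite completes in a few minutes on one core while
still exercising every policy branch; all rates are computed, not
asserted.

## Known limitations

* No PDF ingestion; NXML and plain text only.
* No machine-learning annotators are shipped; the computational layer
  is a hook for external tools.
* Sentence splitting is rule-based; exotic abbreviation patterns not in
  the exception list will over-split.
* The depth-4 folding is one consistent reading of how a browsable
  shallow hierarchy should map onto deep ontologies; other mappings
  (e.g. keeping deep terms invisible but searchable by id only) are
  possible.
* Multi-word surface forms whose tokens are separated by characters
  other than whitespace or a single hyphen do not match across that
  separator.
* The store is single-writer; there is no annotation versioning or
  concurrent multi-user support.
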