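test_that("index bookkeeping: N, df tables, postings", {
  sc <- small_corpus()
  idx <- sc$index
  expect_identical(idx$N, 2L)
  expect_identical(unname(idx$kw_df["kinase"]), 1L)
  expect_identical(unname(idx$kw_df["the"]), 2L)
  expect_identical(unname(idx$cat_df["cat:genes"]), 1L)
  # category sentence ordinals
  lex <- idx$docs[["D1"]]$lexical
  expect_setequal(lex$sent[lex$category_id == "cat:genes"], c(0L, 1L))
  expect_error(build_index(list(sc$docs[[1]], sc$docs[[1]])),
               "duplicate doc_id")
})

test_that("query grammar: precedence, phrases, round-trip, errors", {
  a <- parse_query('"DNA binding" AND enhancer')
  expect_identical(a$type, "and")
  expect_identical(a$args[[1]],
                   list(type = "phrase", tokens = c("dna", "binding")))
  expect_identical(a$args[[2]], list(type = "term", tokens = "enhancer"))

  b <- parse_query("a OR b AND c")  # AND binds tighter
  expect_identical(b$type, "or")
  expect_identical(b$args[[2]]$type, "and")

  c1 <- parse_query("(a OR b) AND c")
  expect_identical(c1$type, "and")
  expect_identical(c1$args[[1]]$type, "or")

  expect_identical(parse_query("NOT x AND y")$args[[1]]$type, "not")
  expect_error(parse_query('"unclosed phrase'),
               class = "litmine_syntax_error")
  expect_error(parse_query("(a OR b"), class = "litmine_syntax_error")
  expect_error(parse_query("a)"), class = "litmine_syntax_error")
  expect_error(parse_query("  "), class = "litmine_syntax_error")
  expect_error(parse_query("a AND OR b"), class = "litmine_syntax_error")

  # print/parse identity on random ASTs
  set.seed(41)
  vocab <- rand_vocab()
  for (rep in 1:50) {
    ast <- rand_ast(vocab, depth = 3L)
    expect_identical(parse_query(format_query(ast)), ast)
  }
})

test_that("query object invariants", {
  expect_error(lit_query(), class = "litmine_invalid_input")
  expect_error(lit_query("NOT x"), class = "litmine_invalid_input")
  expect_error(lit_query("x", filters = list(bogus = 1)),
               class = "litmine_invalid_input")
})

test_that("sentence and document scope behave per contract", {
  sc <- small_corpus()
  # sentence scope: both terms must share a sentence
  q1 <- lit_query("kinase AND essential", scope = "sentence")
  r1 <- search_index(sc$index, q1, sc$forest)
  expect_identical(r1$n_docs, 1L)
  expect_identical(r1$hits[[1]]$sentences$sentence, 1L)
  # terms split across sentences match at document scope only
  q2 <- lit_query("phosphorylates AND essential", scope = "sentence")
  expect_identical(search_index(sc$index, q2, sc$forest)$n_docs, 0L)
  q3 <- lit_query("phosphorylates AND essential", scope = "document")
  expect_identical(search_index(sc$index, q3, sc$forest)$n_docs, 1L)
  # no match anywhere
  q4 <- lit_query("nonexistentword", scope = "document")
  expect_identical(search_index(sc$index, q4, sc$forest)$n_docs, 0L)
  # unknown category errors; empty-result subcorpus warns
  expect_error(search_index(sc$index,
                            lit_query(categories = list("no:such")),
                            sc$forest),
               class = "litmine_not_found")
  expect_warning(
    r <- search_index(sc$index,
                      lit_query("kinase",
                                filters = list(subcorpus = "Astronomy")),
                      sc$forest),
    "unknown sub-corpus")
  expect_identical(r$n_docs, 0L)
})

test_that("multi-category sentence conjunction follows the case-study rule", {
  sc <- small_corpus()
  q <- lit_query(categories = list(list(id = "cat:enzymatic"),
                                   list(id = "cat:genes")),
                 scope = "sentence")
  r <- search_index(sc$index, q, sc$forest)
  expect_identical(r$n_docs, 1L)
  # the only sentence holding both an enzymatic and a gene annotation
  expect_identical(r$hits[[1]]$sentences$sentence, 1L)
  lex <- sc$index$docs[["D1"]]$lexical
  for (s in r$hits[[1]]$sentences$sentence) {
    expect_true(any(lex$sent == s & lex$category_id == "cat:enzymatic"))
    expect_true(any(lex$sent == s & lex$category_id == "cat:genes"))
  }
})

test_that("scoring matches the pinned formula and normalization contract", {
  # single term, tf = 1, df = 1, N = 2: raw = 1 * ln(1 + 2/2) = ln 2
  d1 <- text_doc("alpha beta.", accession = "S1")
  d2 <- text_doc("gamma delta.", accession = "S2")
  forest <- termlist_forest(x = "unusedform")
  tree <- build_lexicon_tree(forest)
  idx <- build_index(list(annotate_document(d1, tree),
                          annotate_document(d2, tree)))
  r <- search_index(idx, lit_query("alpha", scope = "document"), forest)
  expect_equal(r$hits[[1]]$raw_score, log(2), tolerance = 1e-15)
  expect_identical(r$hits[[1]]$doc_score, 1)
  # tfidf_weight contract
  expect_identical(tfidf_weight(0, 5, 10), 0)
  expect_equal(tfidf_weight(1, 1, 2), log(2))
  expect_equal(tfidf_weight(3, 2, 10), (1 + log(3)) * log(1 + 10 / 3))
})

test_that("sorting modes and tie-breaks respect the result invariants", {
  set.seed(51)
  vocab <- rand_vocab()
  forest <- rand_forest(vocab, n_cat = 2L, n_forms = 6L)
  tree <- build_lexicon_tree(forest)
  docs <- lapply(1:6, function(i) {
    d <- text_doc(rand_text(vocab, rand_int(2L, 5L)),
                  accession = sprintf("Y%02d", i),
                  year = c(2010L, 2017L, 2015L, 2017L, NA, 2011L)[i])
    annotate_document(d, tree)
  })
  idx <- build_index(docs)
  q <- lit_query("the OR cell OR gene OR protein", scope = "document",
                 sort = "year")
  r <- search_index(idx, q, forest)
  if (r$n_docs > 1) {
    yrs <- vapply(r$hits, function(h)
      if (is.na(h$year)) -Inf else as.numeric(h$year), numeric(1))
    expect_true(all(diff(yrs) <= 0))
    sc <- vapply(r$hits, `[[`, 0, "doc_score")
    for (i in seq_len(length(yrs) - 1))
      if (yrs[i] == yrs[i + 1]) expect_gte(sc[i], sc[i + 1])
  }
  r2 <- sort_results(r, "score")
  expect_setequal(vapply(r2$hits, `[[`, "", "doc_id"),
                  vapply(r$hits, `[[`, "", "doc_id"))
  scores <- vapply(r2$hits, `[[`, 0, "doc_score")
  expect_true(all(diff(scores) <= 0))
  expect_identical(max(scores), 1)
})

test_that("filters only shrink results; exclusion never adds a unit", {
  sc <- small_corpus()
  base <- search_index(sc$index, lit_query("the", scope = "sentence"),
                       sc$forest)
  base_ids <- vapply(base$hits, `[[`, "", "doc_id")
  for (f in list(list(journal = "Genes"), list(year = 2015),
                 list(author = "nobody"), list(accession = "D1"))) {
    r <- search_index(sc$index,
                      lit_query("the", scope = "sentence", filters = f),
                      sc$forest)
    expect_true(all(vapply(r$hits, `[[`, "", "doc_id") %in% base_ids))
    expect_lte(r$n_sentences, base$n_sentences)
  }
  r_ex <- search_index(
    sc$index,
    lit_query("the", scope = "sentence",
              filters = list(exclude = "kinase")), sc$forest)
  expect_lte(r_ex$n_sentences, base$n_sentences)
  # the excluded keyword's sentence is gone
  d1hits <- r_ex$hits[vapply(r_ex$hits, `[[`, "", "doc_id") == "D1"]
  if (length(d1hits))
    expect_false(1L %in% d1hits[[1]]$sentences$sentence)
})

test_that("section filter restricts units via section annotations", {
  xml <- paste0(
    "<article><front><article-meta>",
    '<article-id pub-id-type="pmid">SEC1</article-id>',
    "<title-group><article-title>Sectioned paper</article-title>",
    "</title-group></article-meta></front><body>",
    "<sec><title>Introduction</title><p>Alpha beta gamma.</p></sec>",
    "<sec><title>Methods</title><p>Alpha delta here.</p></sec>",
    "</body></article>")
  doc <- convert_article(parse_nxml(xml))
  forest <- termlist_forest(x = "unusedform")
  doc <- annotate_document(doc, build_lexicon_tree(forest))
  idx <- build_index(list(doc))
  r_all <- search_index(idx, lit_query("alpha", scope = "sentence"),
                        forest)
  expect_identical(r_all$n_sentences, 2L)
  r_meth <- search_index(
    idx, lit_query("alpha", scope = "sentence",
                   filters = list(section = "methods")), forest)
  expect_identical(r_meth$n_sentences, 1L)
})

test_that("index JSON round-trips and search results are unchanged", {
  sc <- small_corpus()
  p <- withr::local_tempfile(fileext = ".json")
  index_save(sc$index, p)
  idx2 <- index_load(p)
  q <- lit_query("kinase OR dna", scope = "sentence")
  r1 <- search_index(sc$index, q, sc$forest)
  r2 <- search_index(idx2, q, sc$forest)
  expect_equal(r1, r2)
})
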