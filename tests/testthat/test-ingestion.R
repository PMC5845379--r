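test_that("tokenizer handles internal separators and edge cases", {
  t <- tokenize("zyg-1 gene")
  expect_identical(token_texts("zyg-1 gene", t), c("zyg-1", "gene"))
  expect_identical(nrow(tokenize("")), 0L)
  expect_identical(nrow(tokenize("  ... !! ")), 0L)
  # separators are internal only when flanked by letters/digits
  expect_identical(token_texts("end. Next", tokenize("end. Next")),
                   c("end", "Next"))
  expect_identical(token_texts("a--b a-b e.g. 3.5", tokenize("a--b a-b e.g. 3.5")),
                   c("a", "b", "a-b", "e.g", "3.5"))
})

test_that("tokenization satisfies the re-scan oracle on random text", {
  set.seed(11)
  for (rep in 1:25) {
    txt <- rand_text(rand_vocab(), rand_int(1L, 6L))
    toks <- tokenize(txt)
    # concatenating covered tokens equals the text stripped of
    # non-token characters (re-scan with a character-class automaton,
    # mirroring the internal-separator rule)
    cover <- paste(token_texts(txt, toks), collapse = "")
    chars <- strsplit(txt, "")[[1]]
    keep <- grepl("[[:alnum:]]", chars)
    for (i in which(chars %in% c("-", ".", "/", "_", "'")))
      if (i > 1 && i < length(chars) && grepl("[[:alnum:]]", chars[i - 1]) &&
          grepl("[[:alnum:]]", chars[i + 1])) keep[i] <- TRUE
    expect_identical(cover, paste(chars[keep], collapse = ""))
    # spans sorted, non-overlapping
    if (nrow(toks) > 1)
      expect_true(all(toks$begin[-1] >= toks$end[-nrow(toks)]))
  }
})

test_that("sentence splitting respects abbreviation exceptions", {
  txt <- "ZYG-1 acts in C. elegans embryos. It is a kinase."
  s <- split_sentences(txt)
  expect_identical(nrow(s), 2L)
  expect_identical(substring(txt, s$begin + 1, s$end),
                   c("ZYG-1 acts in C. elegans embryos.",
                     "It is a kinase."))
  expect_identical(nrow(split_sentences("One sentence")), 1L)
  # exceptions: Fig. before a digit, e.g. before uppercase
  txt2 <- "See Fig. 3 and Figs. 4 here. Real boundary. Done now."
  s2 <- split_sentences(txt2)
  expect_identical(nrow(s2), 3L)
  txt3 <- "We used e.g. HeLa cells. Controls et al. Agreed too."
  s3 <- split_sentences(txt3)
  expect_identical(substring(txt3, s3$begin + 1, s3$end)[1],
                   "We used e.g. HeLa cells.")
  # every token lies in exactly one sentence
  toks <- tokenize(txt2)
  inside <- vapply(seq_len(nrow(toks)), function(i)
    sum(s2$begin <= toks$begin[i] & s2$end >= toks$end[i]), integer(1))
  expect_true(all(inside == 1L))
})

test_that("NXML parsing recovers front matter and flattens markup", {
  xml <- paste0(
    '<article xmlns:xlink="http://www.w3.org/1999/xlink" ',
    'article-type="research-article"><front><journal-meta>',
    "<journal-title-group><journal-title>Genes</journal-title>",
    "</journal-title-group></journal-meta><article-meta>",
    '<article-id pub-id-type="pmid">12345</article-id>',
    "<title-group><article-title>Population genetics of ",
    "<italic>X</italic></article-title></title-group>",
    '<contrib-group><contrib contrib-type="author"><name>',
    "<surname>Smith</surname><given-names>Ann</given-names></name>",
    "</contrib></contrib-group>",
    "<pub-date><year>2015</year></pub-date>",
    "<article-categories><subj-group><subject>Genetics</subject>",
    "</subj-group></article-categories>",
    "</article-meta></front><body>",
    "<sec><title>Results</title><p>First paragraph with a callout ",
    '<xref rid="b1">[1]</xref> inside.</p><p>Second paragraph.</p></sec>',
    '<fig id="f1"><caption><p>Table 1 Comparison of approaches.</p>',
    '</caption><graphic xlink:href="f1.jpg"/></fig>',
    "</body></article>")
  art <- parse_nxml(xml)
  expect_identical(art$title, "Population genetics of X")
  expect_identical(art$journal, "Genes")
  expect_identical(art$year, 2015L)
  expect_identical(art$authors, "Ann Smith")
  expect_identical(art$accession, "12345")
  expect_identical(art$abstract, "")  # missing optional field
  expect_identical(length(art$blocks), 2L)
  expect_identical(art$blocks[[1]]$text,
                   "First paragraph with a callout [1] inside.")
  expect_identical(art$figures[[1]]$href, "f1.jpg")
  expect_error(parse_nxml("<article><front>"),
               class = "litmine_parse_error")

  doc <- convert_article(art)
  expect_identical(doc$stage, 1L)
  paras <- doc_layer(doc, "paragraph")
  expect_identical(nrow(paras), 4L)  # title + 2 body + caption
  img <- doc_layer(doc, "image")
  expect_identical(covered_text(doc, img[1, ]),
                   "Table 1 Comparison of approaches.")
  expect_identical(unname(img$attributes[[1]]["graphic"]), "f1.jpg")
  secs <- doc_layer(doc, "section")
  labels <- vapply(secs$attributes, function(a) unname(a["label"]), "")
  expect_identical(labels, c("title", "Results", "figures"))
})

test_that("plain-text conversion yields the expected layers", {
  doc <- text_doc("Hello world.")
  expect_identical(nrow(doc_layer(doc, "paragraph")), 1L)
  expect_identical(nrow(doc_layer(doc, "sentence")), 1L)
  expect_identical(nrow(doc_layer(doc, "token")), 2L)
  validate_document(doc)
  # conversion is deterministic
  expect_identical(canon_doc(text_doc("Hello world.")), canon_doc(doc))
})

test_that("token/sentence/paragraph partition invariants hold after convert", {
  set.seed(13)
  for (rep in 1:10) {
    doc <- rand_doc(rand_vocab(), n_para = 3L)
    toks <- doc_layer(doc, "token")
    sents <- doc_layer(doc, "sentence")
    paras <- doc_layer(doc, "paragraph")
    for (tab in list(sents, paras)) {
      inside <- vapply(seq_len(nrow(toks)), function(i)
        sum(tab$begin <= toks$begin[i] & tab$end >= toks$end[i]),
        integer(1))
      expect_true(all(inside == 1L))
    }
    expect_silent(validate_document(doc))
  }
})
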