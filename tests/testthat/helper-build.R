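# Shared builders for small in-code fixtures.

text_doc <- function(text, accession = "T1", title = "", journal = "",
                     year = NA_integer_, subjects = character()) {
  convert_article(text, bibliography(accession, title = title,
                                     journal = journal, year = year,
                                     subjects = subjects))
}

termlist_forest <- function(...) {
  reset_category_ids()
  lists <- list(...)
  do.call(merge_forests, lapply(names(lists), function(nm)
    category_from_termlist(nm, lists[[nm]], id = paste0("cat:", nm))))
}

# canonical view of a document for equality checks: sorted annotation
# table with name-sorted attribute vectors
canon_doc <- function(doc) {
  anns <- doc$annotations
  anns <- anns[order(anns$begin, anns$end, anns$layer, anns$ann_id), ]
  rownames(anns) <- NULL
  anns$attributes <- lapply(anns$attributes, function(a)
    if (length(a)) a[order(names(a))] else character())
  list(doc_id = doc$doc_id, sofa = doc$sofa, bib = doc$bibliography,
       anns = anns, subcorpora = sort(unique(doc$subcorpora)),
       stage = doc$stage)
}

lex_table <- function(doc) {
  lex <- doc_layer(doc, "lexical")
  if (!nrow(lex))
    return(data.frame(begin = integer(), end = integer(),
                      category_id = character(),
                      stringsAsFactors = FALSE))
  out <- data.frame(begin = lex$begin, end = lex$end,
                    category_id = vapply(lex$attributes, function(a)
                      unname(a[["category_id"]]), character(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$begin, out$end, out$category_id), ]
  rownames(out) <- NULL
  out
}

# a small realistic forest + annotated two-document corpus used by
# several search tests
small_corpus <- function() {
  forest <- termlist_forest(
    enzymatic = c("kinase\tkinase activity", "protease activity"),
    genes = c("ZYG-1", "SAS-6"))
  tree <- build_lexicon_tree(forest)
  d1 <- text_doc(paste0("ZYG-1 phosphorylates SAS-6 in embryos. ",
                        "The kinase activity of ZYG-1 is essential."),
                 accession = "D1", title = "Centriole duplication",
                 journal = "Genes", year = 2015)
  d2 <- text_doc(paste0("Transcription factors bind DNA. ",
                        "Enhancer elements recruit the machinery."),
                 accession = "D2", title = "Gene regulation",
                 journal = "Genome Medicine", year = 2017)
  d1 <- annotate_document(d1, tree)
  d2 <- annotate_document(d2, tree)
  list(forest = forest, tree = tree, docs = list(d1, d2),
       index = build_index(list(d1, d2)))
}
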