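# Randomized case generators (all driven by an explicit seed).

rand_int <- function(lo, hi) if (hi <= lo) lo else
  lo + sample.int(hi - lo + 1L, 1L) - 1L

# vocabulary for random documents/lexica: short words, some hyphenated
# and case-marked forms to exercise the matching policies
rand_vocab <- function(n = 25L) {
  base <- c("kinase", "activity", "gene", "protein", "binding", "cell",
            "embryo", "domain", "signal", "pathway", "mutant", "strain",
            "dna", "rna", "enzyme", "factor", "growth", "tissue",
            "membrane", "nucleus", "division", "cycle", "repair",
            "fusion", "motif")
  base[seq_len(min(n, length(base)))]
}

rand_sentence_words <- function(vocab) {
  k <- rand_int(3L, 9L)
  w <- sample(vocab, k, replace = TRUE)
  # occasional hyphen joins and case variants
  if (runif(1) < 0.3 && k >= 2L) {
    i <- rand_int(1L, k - 1L)
    w[i] <- paste0(w[i], "-", w[i + 1L])
    w <- w[-(i + 1L)]
  }
  if (runif(1) < 0.3) {
    i <- rand_int(1L, length(w))
    w[i] <- c(toupper(w[i]),
              paste0(toupper(substr(w[i], 1, 1)), substring(w[i], 2)),
              paste0(w[i], "-", rand_int(1L, 9L)))[rand_int(1L, 3L)]
  }
  substr(w[1L], 1L, 1L) <- toupper(substr(w[1L], 1L, 1L))
  w
}

rand_text <- function(vocab, n_sent = rand_int(1L, 8L), n_para = 1L) {
  paras <- vapply(seq_len(n_para), function(p) {
    paste(vapply(seq_len(n_sent), function(s)
      paste0(paste(rand_sentence_words(vocab), collapse = " "), "."),
      character(1)), collapse = " ")
  }, character(1))
  paste(paras, collapse = "\n\n")
}

rand_doc <- function(vocab, accession = "R1", n_sent = rand_int(1L, 8L),
                     n_para = rand_int(1L, 3L)) {
  text_doc(rand_text(vocab, n_sent, n_para), accession = accession)
}

# random lexicon as a category forest: forms of 1-3 vocabulary words,
# prefixes shared on purpose so the all-matches policy is exercised
rand_forest <- function(vocab, n_cat = rand_int(1L, 4L),
                        n_forms = rand_int(1L, 12L)) {
  reset_category_ids()
  lists <- list()
  for (ci in seq_len(n_cat)) {
    forms <- vapply(seq_len(n_forms), function(i) {
      w <- sample(vocab, rand_int(1L, 3L), replace = FALSE)
      form <- paste(w, collapse = " ")
      if (runif(1) < 0.25) form <- gsub(" ", "-", form)
      if (runif(1) < 0.2)
        form <- c(toupper(form), paste0(form, "-", rand_int(1L, 9L)),
                  sub("^(.)", "\\U\\1", form, perl = TRUE))[rand_int(1L, 3L)]
      form
    }, character(1))
    lists[[paste0("rc", ci)]] <- unique(forms)
  }
  do.call(termlist_forest, lists)
}

# random boolean AST in the canonical shape the parser produces
rand_ast <- function(vocab, depth = 2L, allow_not = TRUE) {
  choice <- if (depth <= 0L) "leaf" else
    sample(c("leaf", "and", "or", if (allow_not) "not"), 1L,
           prob = c(0.45, 0.2, 0.2, if (allow_not) 0.15))
  if (choice == "leaf") {
    if (runif(1) < 0.3) {
      k <- rand_int(2L, 3L)
      return(list(type = "phrase",
                  tokens = sample(vocab, k, replace = TRUE)))
    }
    return(list(type = "term", tokens = sample(vocab, 1L)))
  }
  if (choice == "not")
    return(list(type = "not", arg = rand_ast(vocab, 0L)))
  k <- rand_int(2L, 3L)
  forbid <- choice   # parser never nests and-in-and / or-in-or directly
  args <- lapply(seq_len(k), function(i) {
    repeat {
      a <- rand_ast(vocab, depth - 1L)
      if (!identical(a$type, forbid)) return(a)
    }
  })
  list(type = choice, args = args)
}

rand_query <- function(vocab, cat_ids, with_filters = TRUE,
                       fields = NULL) {
  keywords <- if (runif(1) < 0.75 || !length(cat_ids)) {
    repeat {
      a <- rand_ast(vocab, depth = 2L)
      if (!identical(a$type, "not")) break
    }
    a
  } else NULL
  cats <- list()
  if (length(cat_ids) && runif(1) < 0.6) {
    k <- rand_int(1L, min(3L, length(cat_ids)))
    for (id in sample(cat_ids, k))
      cats[[length(cats) + 1L]] <- list(id = id,
                                        children = runif(1) < 0.5)
  }
  if (is.null(keywords) && !length(cats))
    cats <- list(list(id = sample(cat_ids, 1L), children = FALSE))
  filters <- list()
  if (with_filters && !is.null(fields)) {
    if (runif(1) < 0.2)
      filters$journal <- sample(fields$journal, 1L)
    if (runif(1) < 0.2) {
      y <- fields$year[!is.na(fields$year)]
      if (length(y)) {
        lo <- sample(y, 1L)
        filters$year <- if (runif(1) < 0.5) lo else c(lo, lo + 10L)
      }
    }
    if (runif(1) < 0.15)
      filters$subcorpus <- sample(c("Genetics", "Genomics", "Medicine"),
                                  1L)
    if (runif(1) < 0.25)
      filters$exclude <- sample(vocab, rand_int(1L, 2L))
  }
  lit_query(keywords = keywords, categories = cats,
            scope = sample(c("sentence", "document"), 1L),
            filters = filters,
            sort = sample(c("score", "year"), 1L))
}

# random valid annotations over non-constrained layers, for round-trips
rand_annotations <- function(doc, n) {
  len <- nchar(doc$sofa)
  begin <- sample.int(len - 1L, n, replace = TRUE) - 1L
  end <- pmin(len, begin + sample.int(20L, n, replace = TRUE))
  layer <- sample(c("paragraph", "section", "image", "manual",
                    "computational"), n, replace = TRUE)
  attrs <- lapply(seq_len(n), function(i) {
    k <- rand_int(0L, 3L)
    if (!k) return(character())
    structure(replicate(k, paste(sample(letters, 5), collapse = "")),
              names = paste0("k", seq_len(k)))
  })
  annotations(layer = layer, begin = begin, end = end, attributes = attrs)
}
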