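# Independent brute-force oracles used to cross-check the trie matcher,
# the index/search path, and the scoring formula.

rx_escape <- function(x) gsub("([^A-Za-z0-9 ])", "\\\\\\1", x, perl = TRUE)

# word units of a surface form: tokens, then split at hyphens
form_units <- function(form) {
  toks <- tokenize(form)
  txts <- substring(form, toks$begin + 1L, toks$end)
  unlist(strsplit(txts, "-", fixed = TRUE))
}

form_pattern <- function(form, case_sensitive) {
  units <- form_units(form)
  body <- paste(vapply(units, rx_escape, ""), collapse = "(\\s+|-)")
  paste0(if (!case_sensitive) "(?i)", "^", body, "$")
}

# all-window brute-force matcher over whole-token windows, per sentence
oracle_annotate <- function(doc, lexicon, max_units = 6L) {
  toks <- doc_layer(doc, "token")
  sents <- doc_layer(doc, "sentence")
  pats <- vapply(seq_len(nrow(lexicon)), function(i)
    form_pattern(lexicon$surface_form[i], lexicon$case_sensitive[i]),
    character(1))
  rows <- list()
  for (s in seq_len(nrow(sents))) {
    st <- toks[toks$begin >= sents$begin[s] & toks$end <= sents$end[s], ,
               drop = FALSE]
    n <- nrow(st)
    if (!n) next
    wb <- integer(); we <- integer()
    for (i in seq_len(n))
      for (j in i:min(n, i + max_units - 1L)) {
        wb <- c(wb, st$begin[i]); we <- c(we, st$end[j])
      }
    wtxt <- substring(doc$sofa, wb + 1L, we)
    for (k in seq_len(nrow(lexicon))) {
      hit <- grepl(pats[k], wtxt, perl = TRUE)
      for (w in which(hit))
        rows[[length(rows) + 1L]] <-
          data.frame(begin = wb[w], end = we[w],
                     category_id = lexicon$category_id[k],
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(begin = integer(), end = integer(),
                      category_id = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[!duplicated(paste(out$begin, out$end, out$category_id)), ]
  out <- out[order(out$begin, out$end, out$category_id), ]
  rownames(out) <- NULL
  out
}

forest_lexicon <- function(forest) {
  do.call(rbind, lapply(names(forest$nodes), function(id) {
    lx <- forest$nodes[[id]]$lexicon
    if (!nrow(lx)) return(NULL)
    data.frame(category_id = id, surface_form = lx$surface_form,
               case_sensitive = lx$case_sensitive,
               stringsAsFactors = FALSE)
  }))
}

# ---- brute-force search evaluation over raw documents ----------------------

# precompute per-document evaluation context from the documents themselves
oracle_doc_ctx <- function(doc) {
  toks <- doc_layer(doc, "token")
  sents <- doc_layer(doc, "sentence")
  tok_sent <- vapply(seq_len(nrow(toks)), function(i) {
    hit <- which(sents$begin <= toks$begin[i] & sents$end >= toks$end[i])
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
  lex <- doc_layer(doc, "lexical")
  lex_sent <- if (nrow(lex)) vapply(seq_len(nrow(lex)), function(i) {
    hit <- which(sents$begin <= lex$begin[i] & sents$end >= lex$end[i])
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1)) else integer()
  secs <- doc_layer(doc, "section")
  sec_labels <- vapply(secs$attributes, function(a)
    tolower(unname(a[["label"]] %||% "")), character(1))
  sent_labels <- lapply(seq_len(nrow(sents)), function(s)
    unique(sec_labels[secs$begin <= sents$begin[s] &
                        secs$end >= sents$end[s]]))
  list(doc_id = doc$doc_id, bib = doc$bibliography,
       subcorpora = doc$subcorpora, n_sent = nrow(sents),
       tok_lower = tolower(substring(doc$sofa, toks$begin + 1L, toks$end)),
       tok_sent = tok_sent,
       lex_cat = if (nrow(lex)) vapply(lex$attributes, function(a)
         unname(a[["category_id"]]), character(1)) else character(),
       lex_sent = lex_sent, sec_labels = unique(sec_labels),
       sent_labels = sent_labels)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

oracle_phrase_count <- function(words, sent_of, phrase, sents = NULL) {
  k <- length(phrase)
  n <- length(words)
  if (n < k) return(0L)
  cnt <- 0L
  for (i in seq_len(n - k + 1L)) {
    if (!is.null(sents) && !(sent_of[i] %in% sents)) next
    if (all(words[i:(i + k - 1L)] == phrase) &&
        length(unique(sent_of[i:(i + k - 1L)])) == 1L)
      cnt <- cnt + 1L
  }
  cnt
}

# tf of a keyword leaf within a unit (sent = NULL means whole document)
oracle_leaf_tf <- function(ctx, leaf, sent = NULL) {
  sel <- if (is.null(sent)) rep(TRUE, length(ctx$tok_lower))
         else !is.na(ctx$tok_sent) & ctx$tok_sent == sent
  if (leaf$type == "term") return(sum(ctx$tok_lower[sel] == leaf$tokens))
  oracle_phrase_count(ctx$tok_lower, ctx$tok_sent, leaf$tokens,
                      sents = if (is.null(sent))
                        unique(ctx$tok_sent) else sent)
}

oracle_eval_ast <- function(ast, ctx, sent = NULL) {
  switch(ast$type,
    term = oracle_leaf_tf(ctx, ast, sent) > 0L,
    phrase = oracle_leaf_tf(ctx, ast, sent) > 0L,
    not = !oracle_eval_ast(ast$arg, ctx, sent),
    and = all(vapply(ast$args, oracle_eval_ast, logical(1), ctx, sent)),
    or = any(vapply(ast$args, oracle_eval_ast, logical(1), ctx, sent)))
}

oracle_cat_tf <- function(ctx, ids, sent = NULL) {
  if (is.null(sent)) return(sum(ctx$lex_cat %in% ids))
  sum(ctx$lex_cat %in% ids & !is.na(ctx$lex_sent) & ctx$lex_sent == sent)
}

oracle_doc_passes_filters <- function(ctx, f, all_subcorpora) {
  b <- ctx$bib
  if (!is.null(f$author) &&
      !any(grepl(tolower(f$author), tolower(b$authors), fixed = TRUE)))
    return(FALSE)
  if (!is.null(f$journal) &&
      !grepl(tolower(f$journal), tolower(b$journal), fixed = TRUE))
    return(FALSE)
  if (!is.null(f$year)) {
    yr <- as.integer(f$year)
    if (is.na(b$year) || b$year < min(yr) || b$year > max(yr))
      return(FALSE)
  }
  if (!is.null(f$accession) && !(b$accession == f$accession ||
                                 ctx$doc_id == f$accession))
    return(FALSE)
  if (!is.null(f$subcorpus)) {
    if (!(f$subcorpus %in% all_subcorpora)) return(FALSE)
    if (!(f$subcorpus %in% ctx$subcorpora)) return(FALSE)
  }
  if (!is.null(f$section) && !(tolower(f$section) %in% ctx$sec_labels))
    return(FALSE)
  TRUE
}

oracle_excluded <- function(ctx, excl_tokens, sent = NULL) {
  for (e in excl_tokens) {
    if (length(e) == 1L) {
      sel <- if (is.null(sent)) rep(TRUE, length(ctx$tok_lower))
             else !is.na(ctx$tok_sent) & ctx$tok_sent == sent
      if (any(ctx$tok_lower[sel] == e)) return(TRUE)
    } else if (oracle_phrase_count(ctx$tok_lower, ctx$tok_sent, e,
                                   sents = if (is.null(sent))
                                     unique(ctx$tok_sent) else sent) > 0L)
      return(TRUE)
  }
  FALSE
}

# result-set oracle: returns sorted unit keys ("doc" or "doc#sent")
oracle_search_units <- function(ctxs, query, forest) {
  f <- query$filters
  all_sub <- unique(unlist(lapply(ctxs, `[[`, "subcorpora")))
  cat_ids <- lapply(query$categories, function(cl) {
    if (cl$children) c(cl$id, forest_descendants_oracle(forest, cl$id))
    else cl$id
  })
  excl <- lapply(as.character(f$exclude %||% character()), function(w) {
    t <- tokenize(w)
    if (!nrow(t)) return(NULL)
    tolower(substring(w, t$begin + 1L, t$end))
  })
  excl <- excl[!vapply(excl, is.null, logical(1))]
  out <- character()
  for (ctx in ctxs) {
    if (!oracle_doc_passes_filters(ctx, f, all_sub)) next
    if (query$scope == "document") {
      ok <- TRUE
      if (!is.null(query$keywords) &&
          !oracle_eval_ast(query$keywords, ctx)) ok <- FALSE
      if (ok) for (ids in cat_ids)
        if (oracle_cat_tf(ctx, ids) == 0L) { ok <- FALSE; break }
      if (ok && oracle_excluded(ctx, excl)) ok <- FALSE
      if (ok) out <- c(out, ctx$doc_id)
    } else {
      sect <- tolower(f$section %||% "")
      for (s in seq_len(ctx$n_sent)) {
        if (nzchar(sect) && !(sect %in% ctx$sent_labels[[s]])) next
        ok <- TRUE
        if (!is.null(query$keywords) &&
            !oracle_eval_ast(query$keywords, ctx, s)) ok <- FALSE
        if (ok) for (ids in cat_ids)
          if (oracle_cat_tf(ctx, ids, s) == 0L) { ok <- FALSE; break }
        if (ok && oracle_excluded(ctx, excl, s)) ok <- FALSE
        if (ok) out <- c(out, paste0(ctx$doc_id, "#", s - 1L))
      }
    }
  }
  sort(out)
}

# descendant walk written independently of the package helper
forest_descendants_oracle <- function(forest, id) {
  out <- character()
  stack <- forest$nodes[[id]]$children
  while (length(stack)) {
    x <- stack[1L]; stack <- stack[-1L]
    out <- c(out, x)
    stack <- c(stack, forest$nodes[[x]]$children)
  }
  out
}

# independent reference implementation of the pinned scoring formula
reference_weight <- function(tf, df, N) {
  if (tf < 1) return(0)
  (1 + log(tf)) * (log1p(N / (1 + df)))
}

reference_doc_score <- function(ctxs, ctx, query, forest) {
  N <- length(ctxs)
  leaves <- list()
  collect <- function(ast) {
    if (is.null(ast)) return()
    if (ast$type %in% c("term", "phrase")) {
      leaves[[length(leaves) + 1L]] <<- ast
    } else if (ast$type %in% c("and", "or")) {
      for (a in ast$args) collect(a)
    }
  }
  collect(query$keywords)
  keys <- vapply(leaves, function(l)
    paste0(l$type, ":", paste(l$tokens, collapse = " ")), character(1))
  leaves <- leaves[!duplicated(keys)]
  s <- 0
  for (l in leaves) {
    df <- if (l$type == "term") {
      sum(vapply(ctxs, function(c) l$tokens %in% c$tok_lower, logical(1)))
    } else {
      min(vapply(l$tokens, function(t)
        sum(vapply(ctxs, function(c) t %in% c$tok_lower, logical(1))),
        numeric(1)))
    }
    s <- s + reference_weight(oracle_leaf_tf(ctx, l), df, N)
  }
  for (cl in query$categories) {
    ids <- if (cl$children)
      c(cl$id, forest_descendants_oracle(forest, cl$id)) else cl$id
    df <- sum(vapply(ctxs, function(c) any(c$lex_cat %in% ids),
                     logical(1)))
    s <- s + reference_weight(oracle_cat_tf(ctx, ids), df, N)
  }
  s
}

# unit keys of a search result, matching oracle_search_units' shape
result_units <- function(res) {
  if (res$scope == "document")
    return(sort(as.character(vapply(res$hits, `[[`, "", "doc_id"))))
  sort(as.character(unlist(lapply(res$hits, function(h)
    paste0(h$doc_id, "#", h$sentences$sentence)))))
}
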