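#' @title Inverted index and boolean keyword/category search
#'
#' @description The indexer collects, per document, the normalized
#' (lowercased) token stream with sentence ordinals and positions, the
#' category annotations of the lexical layer, section spans, and the
#' bibliographic filter fields. Queries combine a boolean keyword
#' expression (AND/OR/NOT, quoted phrases, parentheses) with category
#' clauses (conjoined, optionally expanded to child terms) at sentence or
#' document scope, after bibliographic/sub-corpus/section filtering and
#' keyword exclusion. Hits are ranked by a pinned tf-idf variant,
#' `(1 + ln tf) * ln(1 + N/(1 + df))`, summed over positive clauses and
#' normalized with respect to the highest-scoring document.
#'
#' @name index_search
NULL

#' The pinned tf-idf term weight
#'
#' @param tf occurrence count in the unit (contributes 0 when `tf = 0`).
#' @param df document frequency of the clause.
#' @param N number of indexed documents.
#' @return `(1 + ln tf) * ln(1 + N / (1 + df))` for `tf >= 1`, else 0.
#' @export
tfidf_weight <- function(tf, df, N) {
  ifelse(tf >= 1, (1 + log(tf)) * log(1 + N / (1 + df)), 0)
}

#' Build an inverted index over stage >= 2 documents
#'
#' @param docs list of `litdoc` objects (stage >= 2, unique ids), or a
#'   [corpus_store()] (all stage >= 2 documents are indexed, in sorted id
#'   order).
#' @return an object of class `inverted_index`.
#' @export
build_index <- function(docs) {
  if (inherits(docs, "corpus_store")) {
    store <- docs
    manifest <- store_manifest(store)
    ids <- sort(names(manifest$docs))
    ids <- ids[vapply(ids, function(i)
      (manifest$docs[[i]]$stage %||% 0L) >= 2L, logical(1))]
    docs <- lapply(ids, function(i) store_load(store, i))
  }
  ids <- vapply(docs, `[[`, "", "doc_id")
  if (anyDuplicated(ids))
    stop_litmine("duplicate doc_id: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(vapply(docs, `[[`, 0L, "stage") < 2L))
    stop_litmine("build_index needs stage >= 2 documents",
                 class = "litmine_precondition_error")

  per_doc <- list()
  fields <- list()
  for (doc in docs) {
    toks <- doc_layer(doc, "token")
    sents <- doc_layer(doc, "sentence")
    sent_of <- function(begin, end) {
      hit <- which(sents$begin <= begin & sents$end >= end)
      if (length(hit)) hit[1L] - 1L else NA_integer_
    }
    tok_sent <- vapply(seq_len(nrow(toks)), function(i)
      sent_of(toks$begin[i], toks$end[i]), integer(1))
    tok_tab <- data.frame(
      lower = tolower(token_texts(doc$sofa, toks)),
      begin = toks$begin, end = toks$end,
      sent = tok_sent, pos = seq_len(nrow(toks)) - 1L,
      stringsAsFactors = FALSE)
    lex <- doc_layer(doc, "lexical")
    lex_tab <- data.frame(
      category_id = vapply(lex$attributes, function(a)
        unname(a[["category_id"]]), character(1)),
      term_id = vapply(lex$attributes, function(a)
        if ("term_id" %in% names(a)) unname(a[["term_id"]])
        else NA_character_, character(1)),
      matched_form = vapply(lex$attributes, function(a)
        unname(a[["matched_form"]]), character(1)),
      begin = lex$begin, end = lex$end,
      sent = if (nrow(lex)) vapply(seq_len(nrow(lex)), function(i) {
        hit <- which(sents$begin <= lex$begin[i] & sents$end >= lex$end[i])
        if (length(hit)) hit[1L] - 1L else NA_integer_
      }, integer(1)) else integer(),
      stringsAsFactors = FALSE)
    secs <- doc_layer(doc, "section")
    sec_tab <- data.frame(
      label = vapply(secs$attributes, function(a)
        if ("label" %in% names(a)) unname(a[["label"]]) else "",
        character(1)),
      begin = secs$begin, end = secs$end, stringsAsFactors = FALSE)
    sent_sections <- lapply(seq_len(nrow(sents)), function(s) {
      inside <- sec_tab$begin <= sents$begin[s] & sec_tab$end >= sents$end[s]
      sort(unique(tolower(sec_tab$label[inside])))
    })
    per_doc[[doc$doc_id]] <- list(
      n_sent = nrow(sents),
      sent = data.frame(begin = sents$begin, end = sents$end),
      tokens = tok_tab, lexical = lex_tab, sections = sec_tab,
      sent_sections = sent_sections)
    b <- doc$bibliography
    fields[[length(fields) + 1L]] <- data.frame(
      doc_id = doc$doc_id, accession = b$accession, title = b$title,
      journal = b$journal, year = b$year, article_type = b$article_type,
      authors = I(list(b$authors)), subjects = I(list(b$subjects)),
      subcorpora = I(list(sort(unique(doc$subcorpora)))),
      stringsAsFactors = FALSE)
  }
  fields <- if (length(fields)) do.call(rbind, fields) else
    data.frame(doc_id = character(), accession = character(),
               title = character(), journal = character(),
               year = integer(), article_type = character(),
               authors = I(list()), subjects = I(list()),
               subcorpora = I(list()))
  df_table <- function(values) {
    if (!length(values))
      return(structure(integer(), names = character()))
    tab <- table(values)
    out <- structure(as.integer(tab), names = names(tab))
    out[order(names(out))]
  }
  kw_df <- df_table(unlist(lapply(per_doc, function(d)
    unique(d$tokens$lower))))
  cat_df <- df_table(unlist(lapply(per_doc, function(d)
    unique(d$lexical$category_id))))
  structure(list(N = length(per_doc), doc_ids = names(per_doc),
                 fields = fields, docs = per_doc, kw_df = kw_df,
                 cat_df = cat_df),
            class = "inverted_index")
}

# ---- query language --------------------------------------------------------

ast_term <- function(tok) list(type = "term", tokens = tok)
ast_phrase <- function(toks) list(type = "phrase", tokens = toks)
ast_not <- function(x) list(type = "not", arg = x)
ast_and <- function(args) if (length(args) == 1L) args[[1L]] else
  list(type = "and", args = args)
ast_or <- function(args) if (length(args) == 1L) args[[1L]] else
  list(type = "or", args = args)

query_lex <- function(s) {
  toks <- list()
  i <- 1L; n <- nchr(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(kind = ch, pos = i)
      i <- i + 1L
    } else if (ch == '"') {
      j <- i + 1L
      while (j <= n && substr(s, j, j) != '"') j <- j + 1L
      if (j > n)
        stop_litmine("unbalanced quote at position ", i,
                     class = "litmine_syntax_error")
      toks[[length(toks) + 1L]] <-
        list(kind = "quoted", text = substr(s, i + 1L, j - 1L), pos = i)
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !grepl('^[\\s()"]$', substr(s, j, j), perl = TRUE))
        j <- j + 1L
      toks[[length(toks) + 1L]] <-
        list(kind = "word", text = substr(s, i, j - 1L), pos = i)
      i <- j
    }
  }
  toks
}

normalize_query_tokens <- function(text, pos) {
  t <- tokenize(text)
  if (!nrow(t))
    stop_litmine("query token with no searchable content at position ", pos,
                 class = "litmine_syntax_error")
  tolower(token_texts(text, t))
}

#' Parse a boolean keyword query
#'
#' Grammar: `expr := or_expr`; `or_expr := and_expr (OR and_expr)*`;
#' `and_expr := not_term (AND? not_term)*` (juxtaposition means AND, and
#' AND binds tighter than OR); `not_term := [NOT] atom`;
#' `atom := term | "phrase" | ( expr )`. Operators are uppercase AND / OR /
#' NOT; terms are normalized like document tokens (lowercased); a quoted
#' string (or an unquoted word that normalizes to several tokens) becomes
#' a phrase.
#'
#' @param s query string.
#' @return a query AST (nested lists with a `type` field).
#' @export
parse_query <- function(s) {
  if (!is_string(s) || !nzchar(trimws2(s)))
    stop_litmine("empty query", class = "litmine_syntax_error")
  toks <- query_lex(s)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect_rp <- function(open_pos) {
    t <- peek()
    if (is.null(t) || t$kind != ")")
      stop_litmine("unbalanced parenthesis opened at position ", open_pos,
                   class = "litmine_syntax_error")
    advance()
  }
  parse_atom <- function() {
    t <- peek()
    if (is.null(t))
      stop_litmine("unexpected end of query",
                   class = "litmine_syntax_error")
    if (t$kind == "(") {
      advance()
      e <- parse_or()
      expect_rp(t$pos)
      return(e)
    }
    if (t$kind == "quoted") {
      advance()
      return(ast_phrase(normalize_query_tokens(t$text, t$pos)))
    }
    if (t$kind == "word") {
      if (t$text %in% c("AND", "OR", "NOT"))
        stop_litmine("operator ", t$text,
                     " where a term was expected at position ", t$pos,
                     class = "litmine_syntax_error")
      advance()
      nt <- normalize_query_tokens(t$text, t$pos)
      return(if (length(nt) == 1L) ast_term(nt) else ast_phrase(nt))
    }
    stop_litmine("unexpected ')' at position ", t$pos,
                 class = "litmine_syntax_error")
  }
  parse_not <- function() {
    t <- peek()
    if (!is.null(t) && t$kind == "word" && identical(t$text, "NOT")) {
      advance()
      return(ast_not(parse_atom()))
    }
    parse_atom()
  }
  parse_and <- function() {
    args <- list(parse_not())
    repeat {
      t <- peek()
      if (is.null(t) || t$kind == ")") break
      if (t$kind == "word" && identical(t$text, "OR")) break
      if (t$kind == "word" && identical(t$text, "AND")) advance()
      args[[length(args) + 1L]] <- parse_not()
    }
    ast_and(args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    repeat {
      t <- peek()
      if (is.null(t) || !(t$kind == "word" && identical(t$text, "OR"))) break
      advance()
      args[[length(args) + 1L]] <- parse_and()
    }
    ast_or(args)
  }
  out <- parse_or()
  if (pos <= length(toks))
    stop_litmine("unexpected ')' at position ", toks[[pos]]$pos,
                 class = "litmine_syntax_error")
  out
}

#' Render a query AST back to query-language text
#'
#' `parse_query(format_query(ast))` reproduces the AST exactly.
#'
#' @param ast a query AST.
#' @return a query string.
#' @export
format_query <- function(ast) {
  fmt <- function(node, parent) {
    switch(node$type,
      term = node$tokens,
      phrase = paste0('"', paste(node$tokens, collapse = " "), '"'),
      not = paste0("NOT ", {
        inner <- fmt(node$arg, "not")
        if (node$arg$type %in% c("and", "or")) paste0("(", inner, ")")
        else inner
      }),
      and = {
        parts <- vapply(node$args, function(a) {
          s <- fmt(a, "and")
          if (a$type == "or") paste0("(", s, ")") else s
        }, character(1))
        paste(parts, collapse = " AND ")
      },
      or = {
        parts <- vapply(node$args, function(a) fmt(a, "or"), character(1))
        paste(parts, collapse = " OR ")
      },
      stop_litmine("unknown AST node type: ", node$type))
  }
  fmt(ast, "root")
}

# positive (non-negated) term/phrase leaves of an AST
positive_leaves <- function(ast) {
  if (is.null(ast)) return(list())
  switch(ast$type,
    term = list(ast),
    phrase = list(ast),
    not = list(),
    and = ,
    or = do.call(c, lapply(ast$args, positive_leaves)),
    list())
}

# ---- query object ----------------------------------------------------------

#' Construct a search query
#'
#' @param keywords a query string (parsed with [parse_query()]) or a query
#'   AST, or `NULL`.
#' @param categories list of category clauses, each
#'   `list(id = "...", children = TRUE/FALSE)` (a bare character vector is
#'   promoted with `children = FALSE`). Category clauses are conjoined:
#'   every selected category must be present in the unit.
#' @param scope `"sentence"` or `"document"`: the text unit that must
#'   satisfy the whole query.
#' @param filters named list: `author` (case-insensitive substring),
#'   `journal` (substring), `year` (single value or `c(lo, hi)`),
#'   `accession` (exact), `subcorpus` (label), `section` (label,
#'   case-insensitive), `exclude` (character vector of excluded keywords).
#' @param sort `"score"` or `"year"`.
#' @return an object of class `lit_query`.
#' @export
lit_query <- function(keywords = NULL, categories = list(),
                      scope = c("sentence", "document"),
                      filters = list(), sort = c("score", "year")) {
  scope <- match.arg(scope)
  sort <- match.arg(sort)
  if (is.character(keywords)) keywords <- parse_query(keywords)
  if (is.character(categories))
    categories <- lapply(categories, function(id)
      list(id = id, children = FALSE))
  categories <- lapply(categories, function(cl) {
    if (is.character(cl)) cl <- list(id = cl, children = FALSE)
    list(id = cl$id, children = isTRUE(cl$children))
  })
  if (is.null(keywords) && !length(categories))
    stop_litmine("query needs keywords and/or categories",
                 class = "litmine_invalid_input")
  if (!is.null(keywords) && identical(keywords$type, "not"))
    stop_litmine("NOT cannot be the sole top-level clause",
                 class = "litmine_invalid_input")
  known <- c("author", "journal", "year", "accession", "subcorpus",
             "section", "exclude")
  bad <- setdiff(names(filters), known)
  if (length(bad))
    stop_litmine("unknown filter(s): ", paste(bad, collapse = ", "),
                 class = "litmine_invalid_input")
  structure(list(keywords = keywords, categories = categories,
                 scope = scope, filters = filters, sort = sort),
            class = "lit_query")
}

# ---- evaluation ------------------------------------------------------------

# occurrences of a phrase (consecutive positions, single sentence) in a
# token table; returns data.frame(start_row, end_row)
phrase_occurrences <- function(tok_tab, phrase) {
  k <- length(phrase)
  n <- nrow(tok_tab)
  if (n < k) return(integer(0))
  cand <- which(tok_tab$lower == phrase[1L])
  cand <- cand[cand + k - 1L <= n]
  keep <- vapply(cand, function(i) {
    rows <- i:(i + k - 1L)
    all(tok_tab$lower[rows] == phrase) &&
      all(tok_tab$pos[rows] == tok_tab$pos[i] + 0:(k - 1L)) &&
      length(unique(tok_tab$sent[rows])) == 1L
  }, logical(1))
  cand[keep]
}

# per-unit tf of a keyword leaf; unit = token sub-table
leaf_tf <- function(tok_tab, leaf) {
  if (leaf$type == "term") return(sum(tok_tab$lower == leaf$tokens))
  length(phrase_occurrences(tok_tab, leaf$tokens))
}

eval_ast <- function(ast, tok_tab) {
  switch(ast$type,
    term = any(tok_tab$lower == ast$tokens),
    phrase = length(phrase_occurrences(tok_tab, ast$tokens)) > 0L,
    not = !eval_ast(ast$arg, tok_tab),
    and = all(vapply(ast$args, eval_ast, logical(1), tok_tab)),
    or = any(vapply(ast$args, eval_ast, logical(1), tok_tab)),
    stop_litmine("unknown AST node type: ", ast$type))
}

leaf_key <- function(leaf) paste0(leaf$type, ":",
                                  paste(leaf$tokens, collapse = " "))

resolve_category_clause <- function(idx, clause, forest) {
  id <- clause$id
  known_forest <- !is.null(forest) && id %in% names(forest$nodes)
  if (!known_forest && !(id %in% names(idx$cat_df)))
    stop_litmine("unknown category id '", id, "'",
                 class = "litmine_not_found")
  ids <- id
  if (clause$children) {
    if (!known_forest)
      stop_litmine("child-term expansion for '", id,
                   "' needs the category forest",
                   class = "litmine_invalid_input")
    ids <- c(id, forest_descendants(forest, id))
  }
  ids
}

#' Execute a query against an inverted index
#'
#' Candidate units are the sentences (sentence scope) or documents
#' (document scope) of the filter-satisfying, sub-corpus-restricted
#' document set. A keyword term is true iff present in the unit; a phrase
#' iff its tokens occur at consecutive positions within one sentence of
#' the unit; NOT is complement within the unit. Each category clause is
#' true iff the unit holds at least one lexical annotation of the
#' category (or, with `children = TRUE`, of any forest descendant);
#' category clauses are conjoined with each other and with the keyword
#' expression. Units containing an excluded keyword are removed. Raw
#' tf-idf scores (see [tfidf_weight()]) are summed over positive clauses;
#' document scores are normalized with respect to the highest-scoring
#' returned document.
#'
#' @param idx an `inverted_index`.
#' @param query a [lit_query()].
#' @param forest the `category_forest` used at annotation time (required
#'   for `children = TRUE` clauses and id validation).
#' @return an object of class `search_result`: `hits` (list of per-doc
#'   results with normalized `doc_score` and per-sentence hits), `n_docs`,
#'   `n_sentences`, plus the query echo.
#' @export
search_index <- function(idx, query, forest = NULL) {
  stopifnot(inherits(idx, "inverted_index"), inherits(query, "lit_query"))
  f <- query$filters
  cat_ids <- lapply(query$categories, resolve_category_clause, idx = idx,
                    forest = forest)

  # --- document-level filters
  keep <- rep(TRUE, idx$N)
  fl <- idx$fields
  if (!is.null(f$author))
    keep <- keep & vapply(fl$authors, function(a)
      any(grepl(tolower(f$author), tolower(a), fixed = TRUE)), logical(1))
  if (!is.null(f$journal))
    keep <- keep & grepl(tolower(f$journal), tolower(fl$journal),
                         fixed = TRUE)
  if (!is.null(f$year)) {
    yr <- as.integer(f$year)
    lo <- min(yr); hi <- max(yr)
    keep <- keep & !is.na(fl$year) & fl$year >= lo & fl$year <= hi
  }
  if (!is.null(f$accession))
    keep <- keep & (fl$accession == f$accession | fl$doc_id == f$accession)
  if (!is.null(f$subcorpus)) {
    all_labels <- unique(unlist(fl$subcorpora))
    if (!(f$subcorpus %in% all_labels)) {
      warning("unknown sub-corpus label '", f$subcorpus, "'")
      keep <- rep(FALSE, idx$N)
    } else {
      keep <- keep & vapply(fl$subcorpora, function(s)
        f$subcorpus %in% s, logical(1))
    }
  }
  if (!is.null(f$section))
    keep <- keep & vapply(idx$doc_ids, function(id)
      any(tolower(idx$docs[[id]]$sections$label) == tolower(f$section)),
      logical(1))
  cand_ids <- idx$doc_ids[keep]

  # --- clause df (document frequencies, document granularity)
  leaves <- positive_leaves(query$keywords)
  leaves <- leaves[!duplicated(vapply(leaves, leaf_key, character(1)))]
  kw_df_of <- function(t) {
    v <- idx$kw_df[t]
    if (length(v) != 1L || is.na(v)) 0L else unname(v)
  }
  leaf_dfs <- vapply(leaves, function(l) {
    if (l$type == "term") return(as.numeric(kw_df_of(l$tokens)))
    min(vapply(l$tokens, function(t) as.numeric(kw_df_of(t)), numeric(1)))
  }, numeric(1))
  cat_dfs <- vapply(cat_ids, function(ids)
    sum(vapply(idx$doc_ids, function(d)
      any(idx$docs[[d]]$lexical$category_id %in% ids), logical(1))),
    numeric(1))

  excl <- lapply(as.character(f$exclude %||% character()), function(w) {
    t <- tokenize(w)
    if (!nrow(t)) return(NULL)
    tolower(token_texts(w, t))
  })
  excl <- excl[!vapply(excl, is.null, logical(1))]

  unit_excluded <- function(tok_tab) {
    for (e in excl) {
      if (length(e) == 1L) {
        if (any(tok_tab$lower == e)) return(TRUE)
      } else if (length(phrase_occurrences(tok_tab, e))) return(TRUE)
    }
    FALSE
  }

  unit_raw_score <- function(tok_tab, lex_tab) {
    s <- 0
    for (k in seq_along(leaves))
      s <- s + tfidf_weight(leaf_tf(tok_tab, leaves[[k]]),
                            leaf_dfs[k], idx$N)
    for (k in seq_along(cat_ids))
      s <- s + tfidf_weight(sum(lex_tab$category_id %in% cat_ids[[k]]),
                            cat_dfs[k], idx$N)
    s
  }

  unit_satisfies <- function(tok_tab, lex_tab) {
    if (!is.null(query$keywords) && !eval_ast(query$keywords, tok_tab))
      return(FALSE)
    for (ids in cat_ids)
      if (!any(lex_tab$category_id %in% ids)) return(FALSE)
    TRUE
  }

  unit_matches <- function(tok_tab, lex_tab) {
    out <- list()
    for (l in leaves) {
      if (l$type == "term") {
        rows <- which(tok_tab$lower == l$tokens)
        for (r in rows)
          out[[length(out) + 1L]] <- list(begin = tok_tab$begin[r],
                                          end = tok_tab$end[r],
                                          source = leaf_key(l))
      } else {
        for (r in phrase_occurrences(tok_tab, l$tokens))
          out[[length(out) + 1L]] <-
            list(begin = tok_tab$begin[r],
                 end = tok_tab$end[r + length(l$tokens) - 1L],
                 source = leaf_key(l))
      }
    }
    for (k in seq_along(cat_ids)) {
      rows <- which(lex_tab$category_id %in% cat_ids[[k]])
      for (r in rows)
        out[[length(out) + 1L]] <-
          list(begin = lex_tab$begin[r], end = lex_tab$end[r],
               source = paste0("category:", query$categories[[k]]$id))
    }
    out
  }

  # --- evaluate per document
  hits <- list()
  total_sentences <- 0L
  for (d in cand_ids) {
    dd <- idx$docs[[d]]
    sent_section_ok <- rep(TRUE, dd$n_sent)
    if (!is.null(f$section) && query$scope == "sentence")
      sent_section_ok <- vapply(seq_len(dd$n_sent), function(s)
        tolower(f$section) %in% dd$sent_sections[[s]], logical(1))
    if (query$scope == "sentence") {
      sent_rows <- integer()
      sent_scores <- numeric()
      sent_matches <- list()
      for (s in seq_len(dd$n_sent)) {
        if (!sent_section_ok[s]) next
        tok_s <- dd$tokens[dd$tokens$sent == s - 1L, , drop = FALSE]
        lex_s <- dd$lexical[!is.na(dd$lexical$sent) &
                              dd$lexical$sent == s - 1L, , drop = FALSE]
        if (!unit_satisfies(tok_s, lex_s)) next
        if (unit_excluded(tok_s)) next
        sent_rows <- c(sent_rows, s - 1L)
        sent_scores <- c(sent_scores, unit_raw_score(tok_s, lex_s))
        sent_matches[[length(sent_matches) + 1L]] <-
          unit_matches(tok_s, lex_s)
      }
      if (!length(sent_rows)) next
      doc_raw <- unit_raw_score(dd$tokens, dd$lexical)
      hits[[d]] <- list(doc_id = d, sent = sent_rows,
                        sent_scores = sent_scores,
                        sent_matches = sent_matches, raw = doc_raw)
      total_sentences <- total_sentences + length(sent_rows)
    } else {
      if (!unit_satisfies(dd$tokens, dd$lexical)) next
      if (unit_excluded(dd$tokens)) next
      doc_raw <- unit_raw_score(dd$tokens, dd$lexical)
      # report match-bearing sentences for display
      sent_rows <- integer(); sent_scores <- numeric()
      sent_matches <- list()
      for (s in seq_len(dd$n_sent)) {
        tok_s <- dd$tokens[dd$tokens$sent == s - 1L, , drop = FALSE]
        lex_s <- dd$lexical[!is.na(dd$lexical$sent) &
                              dd$lexical$sent == s - 1L, , drop = FALSE]
        m <- unit_matches(tok_s, lex_s)
        if (!length(m)) next
        sent_rows <- c(sent_rows, s - 1L)
        sent_scores <- c(sent_scores, unit_raw_score(tok_s, lex_s))
        sent_matches[[length(sent_matches) + 1L]] <- m
      }
      hits[[d]] <- list(doc_id = d, sent = sent_rows,
                        sent_scores = sent_scores,
                        sent_matches = sent_matches, raw = doc_raw)
      total_sentences <- total_sentences + length(sent_rows)
    }
  }

  # --- normalization, assembly, sorting
  max_raw <- if (length(hits)) max(vapply(hits, `[[`, 0, "raw")) else 0
  out_hits <- lapply(hits, function(h) {
    row <- idx$fields[idx$fields$doc_id == h$doc_id, , drop = FALSE]
    list(doc_id = h$doc_id, accession = row$accession, title = row$title,
         journal = row$journal, year = row$year,
         article_type = row$article_type,
         raw_score = h$raw,
         doc_score = if (max_raw > 0) h$raw / max_raw else 1,
         sentences = data.frame(sentence = h$sent, score = h$sent_scores),
         sentence_matches = h$sent_matches)
  })
  res <- structure(list(hits = unname(out_hits),
                        n_docs = length(out_hits),
                        n_sentences = total_sentences,
                        scope = query$scope, sort = query$sort),
                   class = "search_result")
  sort_results(res, query$sort)
}

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)

#' Sort a search result by score or year
#'
#' Score sort: normalized document scores non-increasing (ties broken by
#' doc id). Year sort: years non-increasing, ties broken by score
#' descending, then doc id; unknown years sort last.
#'
#' @param res a `search_result`.
#' @param mode `"score"` or `"year"`.
#' @return the result with hits reordered (a permutation: no hit is
#'   gained or lost).
#' @export
sort_results <- function(res, mode = c("score", "year")) {
  mode <- match.arg(mode)
  if (!length(res$hits)) { res$sort <- mode; return(res) }
  ids <- vapply(res$hits, `[[`, "", "doc_id")
  scores <- vapply(res$hits, `[[`, 0, "doc_score")
  if (mode == "score") {
    ord <- order(-scores, ids)
  } else {
    years <- vapply(res$hits, function(h)
      if (is.na(h$year)) -Inf else as.numeric(h$year), numeric(1))
    ord <- order(-years, -scores, ids)
  }
  res$hits <- res$hits[ord]
  res$sort <- mode
  res
}

# ---- index persistence -----------------------------------------------------

df_to_cols <- function(df) {
  cols <- lapply(df, function(col)
    if (is.list(col)) lapply(col, as.list) else as.list(col))
  names(cols) <- names(df)
  cols
}

#' Save / load an inverted index as JSON
#'
#' The serialization is canonical (sorted keys, fixed column order), so
#' identical inputs produce byte-identical index files.
#'
#' @param idx an `inverted_index`.
#' @param path file path.
#' @return `index_save`: path invisibly; `index_load`: the index.
#' @export
index_save <- function(idx, path) {
  docs <- lapply(idx$docs, function(d) {
    list(n_sent = d$n_sent,
         sent = list(begin = as.list(d$sent$begin),
                     end = as.list(d$sent$end)),
         tokens = df_to_cols(d$tokens),
         lexical = df_to_cols(d$lexical),
         sections = df_to_cols(d$sections),
         sent_sections = lapply(d$sent_sections, as.list))
  })
  fields <- df_to_cols(idx$fields)
  json_write_canonical(
    list(N = idx$N, doc_ids = as.list(idx$doc_ids), fields = fields,
         docs = docs,
         kw_df = as.list(structure(as.integer(idx$kw_df),
                                   names = names(idx$kw_df))),
         cat_df = as.list(structure(as.integer(idx$cat_df),
                                    names = names(idx$cat_df)))),
    path)
}

cols_to_df <- function(cols, chr_cols = character(), int_cols = character(),
                       list_cols = character()) {
  out <- list()
  for (nm in names(cols)) {
    v <- cols[[nm]]
    out[[nm]] <- if (nm %in% list_cols) I(lapply(v, as_chr))
    else if (nm %in% int_cols)
      vapply(v, function(e) if (is.null(e)) NA_integer_
             else as.integer(e), integer(1))
    else vapply(v, function(e) if (is.null(e)) NA_character_
                else as.character(e), character(1))
  }
  do.call(data.frame, c(out, stringsAsFactors = FALSE))
}

#' @rdname index_save
#' @export
index_load <- function(path) {
  l <- json_read(path)
  docs <- lapply(l$docs, function(d) {
    list(n_sent = as.integer(d$n_sent),
         sent = data.frame(
           begin = vapply(d$sent$begin, as.integer, integer(1)),
           end = vapply(d$sent$end, as.integer, integer(1))),
         tokens = cols_to_df(d$tokens, int_cols = c("begin", "end", "sent",
                                                    "pos")),
         lexical = cols_to_df(d$lexical, int_cols = c("begin", "end",
                                                      "sent")),
         sections = cols_to_df(d$sections, int_cols = c("begin", "end")),
         sent_sections = lapply(d$sent_sections, as_chr))
  })
  fields <- cols_to_df(l$fields, int_cols = "year",
                       list_cols = c("authors", "subjects", "subcorpora"))
  kw_df <- structure(vapply(l$kw_df, as.integer, integer(1)),
                     names = names(l$kw_df))
  cat_df <- structure(vapply(l$cat_df, as.integer, integer(1)),
                      names = names(l$cat_df))
  structure(list(N = as.integer(l$N), doc_ids = as_chr(l$doc_ids),
                 fields = fields, docs = docs, kw_df = kw_df,
                 cat_df = cat_df),
            class = "inverted_index")
}

#' @export
print.inverted_index <- function(x, ...) {
  cat(sprintf("<inverted_index> %d documents, %d keyword types, %d categories\n",
              x$N, length(x$kw_df), length(x$cat_df)))
  invisible(x)
}

#' @export
print.search_result <- function(x, n = 10L, ...) {
  cat(sprintf("%d documents, %d matching sentences (%s scope, sorted by %s)\n",
              x$n_docs, x$n_sentences, x$scope, x$sort))
  if (!length(x$hits)) return(invisible(x))
  show <- x$hits[seq_len(min(n, length(x$hits)))]
  tab <- data.frame(
    Accession = vapply(show, `[[`, "", "accession"),
    Title = substr(vapply(show, `[[`, "", "title"), 1, 40),
    Journal = vapply(show, `[[`, "", "journal"),
    Year = vapply(show, function(h) h$year %|NA|% NA_integer_, integer(1)),
    Type = vapply(show, `[[`, "", "article_type"),
    Score = round(vapply(show, `[[`, 0, "doc_score"), 4))
  print(tab, row.names = FALSE)
  invisible(x)
}
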