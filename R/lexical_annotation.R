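#' @title Dictionary annotation with a token-sequence lexicon trie
#'
#' @description The lexical annotator matches every category surface form
#' against the token stream of a stage-1 document. Matching is
#' token-based, never substring-based (so "Gene" does not match inside
#' "Generation"): a form matches a stretch of text iff the form's token
#' sequence aligns with consecutive document tokens within one sentence,
#' where hyphenated tokens may be split at their hyphens ("DNA binding"
#' matches "DNA-binding") and the separators between matched units must be
#' whitespace or a single hyphen. All matches starting at a position are
#' reported, not just the longest, and matches from different categories
#' may overlap freely.
#'
#' @name lexical_annotation
NULL

# split token spans at internal hyphens into match units.
# tokens: data.frame(begin,end) 0-based; returns data.frame with
# text, begin, end, tok_start, tok_end.
match_units <- function(text, tokens, hyphen_split = TRUE) {
  if (!nrow(tokens))
    return(data.frame(text = character(), begin = integer(),
                      end = integer(), tok_start = logical(),
                      tok_end = logical()))
  txts <- token_texts(text, tokens)
  out_text <- character(); out_begin <- integer(); out_end <- integer()
  out_ts <- logical(); out_te <- logical()
  for (i in seq_along(txts)) {
    if (hyphen_split && grepl("-", txts[i], fixed = TRUE)) {
      parts <- strsplit(txts[i], "-", fixed = TRUE)[[1]]
      off <- tokens$begin[i]
      for (k in seq_along(parts)) {
        out_text <- c(out_text, parts[k])
        out_begin <- c(out_begin, off)
        out_end <- c(out_end, off + nchr(parts[k]))
        out_ts <- c(out_ts, k == 1L)
        out_te <- c(out_te, k == length(parts))
        off <- off + nchr(parts[k]) + 1L
      }
    } else {
      out_text <- c(out_text, txts[i])
      out_begin <- c(out_begin, tokens$begin[i])
      out_end <- c(out_end, tokens$end[i])
      out_ts <- c(out_ts, TRUE)
      out_te <- c(out_te, TRUE)
    }
  }
  data.frame(text = out_text, begin = out_begin, end = out_end,
             tok_start = out_ts, tok_end = out_te,
             stringsAsFactors = FALSE)
}

# gap between consecutive match units is admissible iff it is a
# whitespace run or a single hyphen.
gap_admissible <- function(text, units, hyphen_split = TRUE) {
  n <- nrow(units)
  if (n < 2L) return(logical(0))
  gaps <- substring(text, units$end[-n] + 1L, units$begin[-1L])
  ok <- grepl("^\\s+$", gaps, perl = TRUE)
  if (hyphen_split) ok <- ok | gaps == "-"
  ok
}

new_trie_node <- function() {
  e <- new.env(parent = emptyenv())
  e$kids <- new.env(parent = emptyenv())
  e$pay <- list()
  e
}

#' Compile a category forest into a lexicon trie
#'
#' Edges are lowercased match units (tokens, split at internal hyphens);
#' terminal nodes hold the payloads (category, surface form, case policy,
#' source term) of every form ending there, so the same form in two
#' categories shares one terminal. Forms that tokenize to zero tokens are
#' skipped with a warning.
#'
#' @param forest a `category_forest`.
#' @param hyphen_split treat a single hyphen as equivalent to whitespace
#'   between match units (default TRUE).
#' @return an object of class `lexicon_tree`.
#' @export
build_lexicon_tree <- function(forest, hyphen_split = TRUE) {
  stopifnot(inherits(forest, "category_forest"))
  root <- new_trie_node()
  n_forms <- 0L
  skipped <- 0L
  for (node in forest$nodes) {
    lex <- node$lexicon
    for (i in seq_len(nrow(lex))) {
      form <- lex$surface_form[i]
      toks <- tokenize(form)
      if (!nrow(toks)) { skipped <- skipped + 1L; next }
      units <- match_units(form, toks, hyphen_split)
      cur <- root
      for (u in tolower(units$text)) {
        nxt <- get0(u, cur$kids)
        if (is.null(nxt)) {
          nxt <- new_trie_node()
          assign(u, nxt, cur$kids)
        }
        cur <- nxt
      }
      cur$pay[[length(cur$pay) + 1L]] <-
        list(category_id = node$category_id, surface_form = form,
             case_sensitive = lex$case_sensitive[i],
             source_id = lex$source_id[i], units = units$text)
      n_forms <- n_forms + 1L
    }
  }
  if (skipped > 0L)
    warning(sprintf("build_lexicon_tree: skipped %d form(s) with no tokens",
                    skipped))
  structure(list(root = root, n_forms = n_forms,
                 hyphen_split = hyphen_split),
            class = "lexicon_tree")
}

#' Look up a surface form in a lexicon trie
#'
#' @param tree a `lexicon_tree`.
#' @param form a surface form.
#' @return list of payloads at the terminal reached by the form's unit
#'   sequence (empty if absent).
#' @export
trie_lookup <- function(tree, form) {
  toks <- tokenize(form)
  if (!nrow(toks)) return(list())
  units <- match_units(form, toks, tree$hyphen_split)
  cur <- tree$root
  for (u in tolower(units$text)) {
    cur <- get0(u, cur$kids)
    if (is.null(cur)) return(list())
  }
  cur$pay
}

#' Mark up category term occurrences in a document
#'
#' Scans each sentence's token sequence and, at each token position,
#' reports all lexicon matches starting there (not just the longest).
#' Matches never cross sentence boundaries; duplicate (span, category)
#' pairs are emitted once; the lexical layer is replaced (re-annotation is
#' idempotent). Each annotation carries `category_id`, `matched_form`,
#' `term_id` and `case_sensitive` attributes and spans whole tokens.
#'
#' @param doc a stage >= 1 `litdoc` (token and sentence layers present).
#' @param tree a [build_lexicon_tree()] trie.
#' @return the document at stage >= 2 with lexical annotations attached.
#' @export
annotate_document <- function(doc, tree) {
  stopifnot(inherits(doc, "litdoc"), inherits(tree, "lexicon_tree"))
  toks <- doc_layer(doc, "token")
  sents <- doc_layer(doc, "sentence")
  if (doc$stage < 1L || !nrow(toks))
    stop_litmine("annotate_document needs a stage >= 1 document with a ",
                 "token layer", class = "litmine_precondition_error")
  doc <- clear_layer(doc, "lexical")
  hits <- list()
  for (s in seq_len(nrow(sents))) {
    st <- toks[toks$begin >= sents$begin[s] & toks$end <= sents$end[s], ,
               drop = FALSE]
    if (!nrow(st)) next
    units <- match_units(doc$sofa, st, tree$hyphen_split)
    gok <- c(TRUE, gap_admissible(doc$sofa, units, tree$hyphen_split))
    lower <- tolower(units$text)
    for (i in which(units$tok_start)) {
      cur <- tree$root
      j <- i
      while (j <= nrow(units)) {
        if (j > i && !gok[j]) break
        cur <- get0(lower[j], cur$kids)
        if (is.null(cur)) break
        if (units$tok_end[j] && length(cur$pay)) {
          for (p in cur$pay) {
            if (p$case_sensitive &&
                !identical(units$text[i:j], p$units)) next
            hits[[length(hits) + 1L]] <-
              list(begin = units$begin[i], end = units$end[j],
                   category_id = p$category_id,
                   matched_form = p$surface_form,
                   source_id = p$source_id,
                   case_sensitive = p$case_sensitive)
          }
        }
        j <- j + 1L
      }
    }
  }
  if (length(hits)) {
    key <- vapply(hits, function(h)
      paste(h$begin, h$end, h$category_id), character(1))
    hits <- hits[!duplicated(key)]
    ord <- order(vapply(hits, `[[`, 0L, "begin"),
                 vapply(hits, `[[`, 0L, "end"),
                 vapply(hits, `[[`, "", "category_id"))
    hits <- hits[ord]
    anns <- annotations(
      layer = rep("lexical", length(hits)),
      begin = vapply(hits, `[[`, 0L, "begin"),
      end = vapply(hits, `[[`, 0L, "end"),
      attributes = lapply(hits, function(h)
        c(category_id = h$category_id, matched_form = h$matched_form,
          term_id = h$source_id,
          case_sensitive = if (h$case_sensitive) "true" else "false")))
    doc <- add_annotations(doc, anns)
  }
  doc$stage <- max(doc$stage, 2L)
  doc
}

# ---- sub-corpus classification ---------------------------------------------

#' Sub-corpus rules
#'
#' A rule is a (label, pattern) pair; a document receives the label iff
#' the regular expression finds a match in its title, journal name, or any
#' subject field. The conventional example: label "Genetics" with pattern
#' `[Gg]enet`.
#'
#' @param label character vector of labels.
#' @param pattern character vector of regular expressions (must compile).
#' @return data frame of rules.
#' @export
subcorpus_rules <- function(label, pattern) {
  stopifnot(length(label) == length(pattern))
  for (p in pattern) {
    ok <- tryCatch({ suppressWarnings(grepl(p, "", perl = TRUE)); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop_litmine("sub-corpus pattern does not compile: ", p,
                          class = "litmine_invalid_input")
  }
  data.frame(label = label, pattern = pattern, stringsAsFactors = FALSE)
}

#' Read sub-corpus rules from a JSON file
#'
#' Format: `[{"label": "...", "pattern": "..."}, ...]`.
#' @param path file path.
#' @return data frame of rules.
#' @export
read_subcorpus_rules <- function(path) {
  l <- json_read(path)
  subcorpus_rules(vapply(l, `[[`, "", "label"),
                  vapply(l, `[[`, "", "pattern"))
}

#' Classify a document into sub-corpora
#'
#' @param doc a `litdoc`.
#' @param rules a [subcorpus_rules()] data frame.
#' @return sorted character vector of matching labels (possibly empty).
#' @export
classify_subcorpus <- function(doc, rules) {
  b <- doc$bibliography
  fields <- c(b$title, b$journal, b$subjects)
  hit <- vapply(seq_len(nrow(rules)), function(i)
    any(grepl(rules$pattern[i], fields, perl = TRUE)), logical(1))
  sort(unique(rules$label[hit]))
}

#' @export
print.lexicon_tree <- function(x, ...) {
  cat(sprintf("<lexicon_tree> %d surface forms (hyphen_split=%s)\n",
              x$n_forms, x$hyphen_split))
  invisible(x)
}
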