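#' @title Categories: ontology-derived lexica in a shallow hierarchy
#'
#' @description Categories are named sets of semantically related surface
#' forms (a lexicon), harvested from OBO ontology term names and synonyms
#' or from custom word lists. For browsing and child-term expansion they
#' are organized into a shallow forest with a maximum depth of four nodes;
#' ontology terms deeper than the cut are not lost — their names and
#' synonyms are folded into the lexicon of their nearest ancestor at the
#' maximum depth, so deep terms remain searchable.
#'
#' @name categories
NULL

.litmine_env <- new.env(parent = emptyenv())
.litmine_env$tpc_counter <- 0L

next_tpc_id <- function() {
  .litmine_env$tpc_counter <- .litmine_env$tpc_counter + 1L
  sprintf("tpc:%07d", .litmine_env$tpc_counter)
}

#' Reset the generated category-id counter (mainly for tests)
#' @return invisibly, the counter value before reset.
#' @export
reset_category_ids <- function() {
  old <- .litmine_env$tpc_counter
  .litmine_env$tpc_counter <- 0L
  invisible(old)
}

#' Parse an OBO flat file
#'
#' Reads `[Term]` stanzas and the tags `id`, `name`, `synonym` (quoted
#' string plus scope), `is_a` (comments after `!` stripped) and
#' `is_obsolete`; other tags are ignored. Obsolete terms and stanzas
#' missing an id or name are dropped (the latter with a warning count).
#'
#' @param x path to an `.obo` file, or a character vector / single string
#'   of OBO text.
#' @return list of ontology terms, each
#'   `list(term_id, name, synonyms = data.frame(text, scope), parents,
#'   obsolete)`.
#' @export
parse_obo <- function(x) {
  if (is_string(x) && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE, encoding = "UTF-8")
  } else if (is.character(x)) {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE))
  } else {
    stop_litmine("x must be a file path or OBO text",
                 class = "litmine_parse_error")
  }
  terms <- list()
  cur <- NULL
  in_term <- FALSE
  skipped <- 0L
  flush <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$term_id) || is.null(cur$name)) {
      skipped <<- skipped + 1L
    } else if (!isTRUE(cur$obsolete)) {
      cur$obsolete <- FALSE
      syn <- cur$synonyms %||% list()
      cur$synonyms <- data.frame(
        text = vapply(syn, `[[`, "", 1L),
        scope = vapply(syn, `[[`, "", 2L),
        stringsAsFactors = FALSE)
      cur$parents <- cur$parents %||% character()
      terms[[length(terms) + 1L]] <<- cur
    }
    cur <<- NULL
  }
  for (ln in lines) {
    ln <- trimws2(sub("^([^!\"]*)!.*$", "\\1", ln, perl = TRUE))
    if (!nzchar(ln)) next
    if (grepl("^\\[", ln)) {
      flush()
      in_term <- identical(ln, "[Term]")
      if (in_term) cur <- list()
      next
    }
    if (!in_term || is.null(cur)) next
    if (grepl("^id:", ln)) {
      cur$term_id <- trimws2(sub("^id:", "", ln))
    } else if (grepl("^name:", ln)) {
      cur$name <- trimws2(sub("^name:", "", ln))
    } else if (grepl("^synonym:", ln)) {
      body <- trimws2(sub("^synonym:", "", ln))
      m <- regmatches(body, regexec('^"((?:[^"\\\\]|\\\\.)*)"\\s*([A-Z]*)',
                                    body, perl = TRUE))[[1]]
      if (length(m) >= 2L && nzchar(m[2])) {
        txt <- gsub('\\\\(.)', "\\1", m[2], perl = TRUE)
        scope <- if (length(m) >= 3L && nzchar(m[3])) m[3] else "RELATED"
        cur$synonyms <- c(cur$synonyms %||% list(), list(c(txt, scope)))
      }
    } else if (grepl("^is_a:", ln)) {
      id <- trimws2(sub("^is_a:", "", ln))
      id <- trimws2(sub("\\{.*\\}", "", id))
      if (nzchar(id)) cur$parents <- c(cur$parents %||% character(), id)
    } else if (grepl("^is_obsolete:", ln)) {
      cur$obsolete <- grepl("true", ln, fixed = TRUE)
    }
  }
  flush()
  if (skipped > 0L)
    warning(sprintf("parse_obo: skipped %d stanza(s) missing id or name",
                    skipped))
  terms
}

#' Case policy for a lexicon surface form
#'
#' A form is matched case-sensitively iff it contains a digit, or an
#' uppercase letter anywhere after its first character (so "ZYG-1" and
#' "DnaK" match exactly, while "kinase" also matches "Kinase" at sentence
#' start).
#'
#' @param form character vector of surface forms.
#' @return logical vector.
#' @export
case_sensitive_form <- function(form) {
  grepl("\\p{N}", form, perl = TRUE) |
    grepl("\\p{Lu}", substring(form, 2L), perl = TRUE)
}

lexicon_frame <- function(surface_form = character(),
                          source_id = character()) {
  data.frame(surface_form = surface_form,
             case_sensitive = case_sensitive_form(surface_form),
             source_id = source_id, stringsAsFactors = FALSE)
}

term_forms <- function(term) {
  forms <- c(term$name,
             if (nrow(term$synonyms)) term$synonyms$text else character())
  forms[nzchar(forms)]
}

#' Compile ontology terms into a depth-limited category forest
#'
#' Reachable terms at depth `<= max_depth` from their root (root = depth 1,
#' breadth-first over `is_a` children, expansion ordered by term id so
#' multi-parent terms attach under the first-reached parent) become
#' category nodes carrying their own name and synonyms as lexicon entries.
#' Terms deeper than `max_depth` contribute their name and synonyms to the
#' lexicon of their nearest ancestor at depth `max_depth` (folded, not
#' lost). Folded forms are deduplicated per node.
#'
#' @param terms list of ontology terms from [parse_obo()].
#' @param roots character vector of root term ids.
#' @param max_depth maximum browsable depth (default 4).
#' @return an object of class `category_forest`: `nodes` (named list of
#'   `list(category_id, name, parent, children, depth, lexicon)`) and
#'   `roots`.
#' @export
build_category_forest <- function(terms, roots, max_depth = 4L) {
  terms <- terms[!vapply(terms, function(t) isTRUE(t$obsolete), logical(1))]
  ids <- vapply(terms, `[[`, "", "term_id")
  if (anyDuplicated(ids))
    stop_litmine("duplicate term ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(terms) <- ids
  missing <- setdiff(roots, ids)
  if (length(missing))
    stop_litmine("unknown root term(s): ", paste(missing, collapse = ", "))
  children <- new.env(parent = emptyenv())
  for (t in terms) {
    for (p in t$parents) {
      if (!p %in% ids) next
      assign(p, c(get0(p, children, ifnotfound = character()), t$term_id),
             children)
    }
  }
  kids_of <- function(id) sort(unique(get0(id, children,
                                           ifnotfound = character())))
  # cycle check over the reachable is_a child graph
  color <- new.env(parent = emptyenv())
  stack_path <- character()
  visit <- function(id) {
    st <- get0(id, color, ifnotfound = 0L)
    if (st == 1L) {
      cyc <- c(stack_path[which(stack_path == id)[1L]:length(stack_path)], id)
      stop_litmine("cycle detected in is_a graph: ",
                   paste(cyc, collapse = " -> "))
    }
    if (st == 2L) return()
    assign(id, 1L, color)
    stack_path <<- c(stack_path, id)
    for (k in kids_of(id)) visit(k)
    stack_path <<- stack_path[-length(stack_path)]
    assign(id, 2L, color)
  }
  for (r in sort(roots)) visit(r)

  depth <- new.env(parent = emptyenv())
  tree_parent <- new.env(parent = emptyenv())
  queue <- sort(roots)
  for (r in queue) { assign(r, 1L, depth); assign(r, NA_character_,
                                                  tree_parent) }
  order_visited <- character()
  while (length(queue)) {
    id <- queue[1L]; queue <- queue[-1L]
    order_visited <- c(order_visited, id)
    d <- get(id, depth)
    for (k in kids_of(id)) {
      if (!is.null(get0(k, depth))) next
      assign(k, d + 1L, depth)
      assign(k, id, tree_parent)
      queue <- c(queue, k)
    }
  }

  nodes <- list()
  for (id in order_visited) {
    d <- get(id, depth)
    if (d > max_depth) next
    nodes[[id]] <- list(category_id = id, name = terms[[id]]$name,
                        parent = get(id, tree_parent),
                        children = character(), depth = d,
                        lexicon = lexicon_frame(term_forms(terms[[id]]),
                                                rep(id, length(
                                                  term_forms(terms[[id]])))))
  }
  for (id in order_visited) {
    d <- get(id, depth)
    if (d <= max_depth) {
      p <- get(id, tree_parent)
      if (!is.na(p)) nodes[[p]]$children <- c(nodes[[p]]$children, id)
      next
    }
    # fold into nearest ancestor at depth == max_depth
    anc <- id
    while (get(anc, depth) > max_depth) anc <- get(anc, tree_parent)
    add <- lexicon_frame(term_forms(terms[[id]]),
                         rep(id, length(term_forms(terms[[id]]))))
    lex <- rbind(nodes[[anc]]$lexicon, add)
    nodes[[anc]]$lexicon <- lex[!duplicated(lex$surface_form), ,
                                drop = FALSE]
  }
  for (id in names(nodes)) {
    lex <- nodes[[id]]$lexicon
    nodes[[id]]$lexicon <- lex[!duplicated(lex$surface_form), , drop = FALSE]
    rownames(nodes[[id]]$lexicon) <- NULL
  }
  structure(list(nodes = nodes, roots = sort(roots),
                 max_depth = as.integer(max_depth)),
            class = "category_forest")
}

parse_termlist_lines <- function(lines) {
  entries <- list()
  for (ln in lines) {
    parts <- trimws2(strsplit(ln, "\t", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    if (!length(parts)) next
    entries[[length(entries) + 1L]] <-
      list(canonical = parts[1L],
           synonyms = if (length(parts) > 1L) parts[-1L] else character())
  }
  entries
}

#' Represent a word list as OBO stanzas
#'
#' Custom term lists enter the same processing pipeline as formal
#' ontologies: each list becomes a root stanza (the category name) plus
#' one child stanza per line (canonical term, tab-separated synonyms,
#' `is_a` the root).
#'
#' @param name category name.
#' @param lines character vector, one canonical term per line with
#'   optional tab-separated synonyms.
#' @param root_id id for the root stanza (auto-generated `tpc:` id when
#'   `NULL`).
#' @return a string of OBO text.
#' @export
termlist_to_obo <- function(name, lines, root_id = NULL) {
  entries <- parse_termlist_lines(lines)
  if (!length(entries))
    stop_litmine("empty term list", class = "litmine_invalid_input")
  if (is.null(root_id)) root_id <- next_tpc_id()
  out <- c("format-version: 1.2", "",
           "[Term]", paste0("id: ", root_id), paste0("name: ", name))
  for (e in entries) {
    out <- c(out, "", "[Term]", paste0("id: ", next_tpc_id()),
             paste0("name: ", e$canonical))
    for (s in e$synonyms)
      out <- c(out, sprintf('synonym: "%s" EXACT []',
                            gsub('"', '\\\\"', s)))
    out <- c(out, paste0("is_a: ", root_id, " ! ", name))
  }
  paste(out, collapse = "\n")
}

#' Compile a custom word list into a single root-level category
#'
#' @inheritParams termlist_to_obo
#' @param id category id; auto-generated `tpc:` id when `NULL`.
#' @return a one-node `category_forest` whose root lexicon holds every
#'   term and synonym (deduplicated).
#' @export
category_from_termlist <- function(name, lines, id = NULL) {
  if (!is_string(name) || !nzchar(name))
    stop_litmine("category name must be a non-empty string",
                 class = "litmine_invalid_input")
  entries <- parse_termlist_lines(lines)
  if (!length(entries))
    stop_litmine("empty term list", class = "litmine_invalid_input")
  if (is.null(id)) id <- next_tpc_id()
  forms <- character(); src <- character()
  for (e in entries) {
    fs <- c(e$canonical, e$synonyms)
    forms <- c(forms, fs)
    src <- c(src, rep(e$canonical, length(fs)))
  }
  keep <- !duplicated(forms)
  lex <- lexicon_frame(forms[keep], paste0(id, "/", src[keep]))
  node <- list(category_id = id, name = name, parent = NA_character_,
               children = character(), depth = 1L, lexicon = lex)
  structure(list(nodes = structure(list(node), names = id), roots = id,
                 max_depth = 1L),
            class = "category_forest")
}

#' Merge category forests (e.g. ontology-derived plus word lists)
#'
#' @param ... `category_forest` objects.
#' @return a single `category_forest`.
#' @export
merge_forests <- function(...) {
  fs <- list(...)
  nodes <- list(); roots <- character(); md <- 1L
  for (f in fs) {
    stopifnot(inherits(f, "category_forest"))
    if (length(intersect(names(nodes), names(f$nodes))))
      stop_litmine("duplicate category ids across forests")
    nodes <- c(nodes, f$nodes)
    roots <- c(roots, f$roots)
    md <- max(md, f$max_depth)
  }
  structure(list(nodes = nodes, roots = sort(roots), max_depth = md),
            class = "category_forest")
}

forest_descendants <- function(forest, category_id) {
  out <- character()
  queue <- forest$nodes[[category_id]]$children
  while (length(queue)) {
    id <- queue[1L]; queue <- queue[-1L]
    out <- c(out, id)
    queue <- c(queue, forest$nodes[[id]]$children)
  }
  out
}

#' Lexicon of a category, optionally expanded with its child terms
#'
#' @param forest a `category_forest`.
#' @param category_id a node id.
#' @param children include the lexica of all forest descendants.
#' @return data frame `surface_form, case_sensitive, source_id, origin`
#'   (origin = the node contributing the form).
#' @export
expand_with_children <- function(forest, category_id, children = TRUE) {
  if (!category_id %in% names(forest$nodes))
    stop_litmine("unknown category id '", category_id, "'",
                 class = "litmine_not_found")
  ids <- c(category_id,
           if (children) forest_descendants(forest, category_id))
  out <- do.call(rbind, lapply(ids, function(id) {
    lex <- forest$nodes[[id]]$lexicon
    if (!nrow(lex)) return(NULL)
    lex$origin <- id
    lex
  }))
  if (is.null(out))
    out <- cbind(lexicon_frame(), origin = character())
  rownames(out) <- NULL
  out
}

# ---- forest serialization --------------------------------------------------

#' Save / load a category forest as JSON
#'
#' @param forest a `category_forest`.
#' @param path file path.
#' @return `forest_save`: the path invisibly; `forest_load`: the forest.
#' @export
forest_save <- function(forest, path) {
  nodes <- lapply(forest$nodes, function(n) {
    list(category_id = n$category_id, name = n$name,
         parent = if (is.na(n$parent)) NULL else n$parent,
         children = as.list(n$children), depth = n$depth,
         lexicon = lapply(seq_len(nrow(n$lexicon)), function(i)
           list(surface_form = n$lexicon$surface_form[i],
                case_sensitive = n$lexicon$case_sensitive[i],
                source_id = n$lexicon$source_id[i])))
  })
  json_write_canonical(list(nodes = nodes, roots = as.list(forest$roots),
                            max_depth = forest$max_depth), path)
}

#' @rdname forest_save
#' @export
forest_load <- function(path) {
  l <- json_read(path)
  nodes <- lapply(l$nodes, function(n) {
    lex <- data.frame(
      surface_form = vapply(n$lexicon, `[[`, "", "surface_form"),
      case_sensitive = vapply(n$lexicon, function(e)
        isTRUE(e$case_sensitive), logical(1)),
      source_id = vapply(n$lexicon, `[[`, "", "source_id"),
      stringsAsFactors = FALSE)
    list(category_id = n$category_id, name = n$name,
         parent = n$parent %||% NA_character_,
         children = as_chr(n$children %||% list()),
         depth = as.integer(n$depth), lexicon = lex)
  })
  names(nodes) <- vapply(nodes, `[[`, "", "category_id")
  structure(list(nodes = nodes, roots = as_chr(l$roots),
                 max_depth = as.integer(l$max_depth %||% 4L)),
            class = "category_forest")
}

#' @export
print.category_forest <- function(x, ...) {
  nf <- sum(vapply(x$nodes, function(n) nrow(n$lexicon), integer(1)))
  cat(sprintf("<category_forest> %d nodes (%d roots), %d surface forms, max depth %d\n",
              length(x$nodes), length(x$roots), nf,
              max(vapply(x$nodes, `[[`, 1L, "depth"))))
  invisible(x)
}
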