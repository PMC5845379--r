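#' @title Standoff-annotation document model
#'
#' @description The document model follows the standoff-annotation
#' convention: the full text of an article (the subject of analysis, or
#' SofA) is an immutable string, and every derived piece of information —
#' tokens, sentences, paragraphs, sections, figure captions, dictionary
#' (lexical) matches, manual curation marks, computational annotations —
#' is a typed span referencing the SofA by character offsets. The SofA is
#' never modified after document creation.
#'
#' Offsets are 0-based, half-open (`begin` inclusive, `end` exclusive),
#' counted in Unicode code points.
#'
#' @name corpus_model
NULL

ANN_LAYERS <- c("token", "sentence", "paragraph", "section", "image",
                "lexical", "manual", "computational")

#' Build an annotation table
#'
#' Annotations are kept in a data frame with one row per annotation:
#' `ann_id` (opaque identifier), `layer`, `begin`, `end` (0-based,
#' half-open) and a list column `attributes` of named character vectors.
#'
#' @param layer character vector of layer names (see `ANN_LAYERS`).
#' @param begin,end integer vectors of 0-based half-open span offsets.
#' @param attributes list of named character vectors, one per annotation
#'   (recycled if a single vector is given).
#' @param ann_id optional character vector of identifiers; `NA` entries are
#'   assigned automatically when added to a document.
#' @return a data frame of annotations.
#' @export
annotations <- function(layer = character(), begin = integer(),
                        end = integer(), attributes = NULL, ann_id = NULL) {
  n <- length(layer)
  stopifnot(length(begin) == n, length(end) == n)
  if (is.null(attributes)) {
    attributes <- rep(list(character()), n)
  } else if (!is.null(names(attributes)) || (is.character(attributes))) {
    attributes <- rep(list(attributes), n)
  }
  stopifnot(length(attributes) == n)
  if (is.null(ann_id)) ann_id <- rep(NA_character_, n)
  data.frame(ann_id = as.character(ann_id), layer = as.character(layer),
             begin = as.integer(begin), end = as.integer(end),
             attributes = I(unname(attributes)),
             stringsAsFactors = FALSE)
}

#' Create a single annotation
#'
#' @inheritParams annotations
#' @return a one-row annotation data frame.
#' @export
annotation <- function(layer, begin, end, attributes = character(),
                       ann_id = NA_character_) {
  annotations(layer, begin, end, list(attributes), ann_id)
}

empty_annotations <- function() annotations()

#' Article bibliography
#'
#' @param accession unique non-empty identifier (e.g. a PMID or a filename
#'   stem); used as the document id.
#' @param title,journal,article_type,abstract strings (may be empty).
#' @param authors character vector of author names in order.
#' @param year 4-digit integer, or `NA` when unknown.
#' @param subjects character vector of subject headings.
#' @return an object of class `bibliography`.
#' @export
bibliography <- function(accession, title = "", authors = character(),
                         journal = "", year = NA_integer_,
                         article_type = "", subjects = character(),
                         abstract = "") {
  if (!is_string(accession) || !nzchar(accession))
    stop_litmine("bibliography accession must be a non-empty string",
                 class = "litmine_invalid_input")
  year <- suppressWarnings(as.integer(year))
  if (length(year) != 1L) year <- NA_integer_
  if (!is.na(year) && (year < 1000L || year > 9999L))
    stop_litmine("bibliography year must be a 4-digit integer or NA",
                 class = "litmine_invalid_input")
  structure(list(accession = accession, title = as.character(title),
                 authors = as.character(authors),
                 journal = as.character(journal), year = year,
                 article_type = as.character(article_type),
                 subjects = as.character(subjects),
                 abstract = as.character(abstract)),
            class = "bibliography")
}

#' Create a stage-0 document
#'
#' @param sofa non-empty full-text string (the subject of analysis).
#' @param bib a [bibliography()] object; its accession becomes the
#'   document id.
#' @return an object of class `litdoc` with an empty annotation table,
#'   empty sub-corpus label set, and `stage = 0`.
#' @export
create_document <- function(sofa, bib) {
  if (!is_string(sofa) || !nzchar(sofa))
    stop_litmine("document SofA must be a non-empty string",
                 class = "litmine_invalid_input")
  if (!inherits(bib, "bibliography"))
    stop_litmine("bib must be a bibliography object",
                 class = "litmine_invalid_input")
  structure(list(doc_id = bib$accession, sofa = enc2utf8(sofa),
                 bibliography = bib, annotations = empty_annotations(),
                 subcorpora = character(), stage = 0L),
            class = "litdoc")
}

ann_label <- function(a) {
  sprintf("%s[%s,%s)%s", a$layer, a$begin, a$end,
          if (!is.na(a$ann_id)) paste0(" id=", a$ann_id) else "")
}

# compare a matched lexicon form against covered text: equal token-wise,
# case-insensitively unless case-sensitive forms compare exactly; hyphen
# and whitespace separators are interchangeable.
form_matches_text <- function(form, text, case_sensitive = FALSE) {
  split1 <- function(x) strsplit(x, "[-\\s]+", perl = TRUE)[[1]]
  a <- split1(form); b <- split1(text)
  if (length(a) != length(b)) return(FALSE)
  if (!case_sensitive) { a <- tolower(a); b <- tolower(b) }
  all(a == b)
}

validate_annotation_rows <- function(doc, anns) {
  len <- nchr(doc$sofa)
  for (i in seq_len(nrow(anns))) {
    a <- anns[i, ]
    if (!(a$layer %in% ANN_LAYERS))
      stop_litmine("unknown annotation layer '", a$layer, "' for ",
                   ann_label(a), class = "litmine_validation_error")
    if (is.na(a$begin) || is.na(a$end) || a$begin < 0L || a$begin >= a$end ||
        a$end > len)
      stop_litmine("annotation span out of range for ", ann_label(a),
                   " (SofA length ", len, ")",
                   class = "litmine_validation_error")
    if (a$layer == "lexical") {
      at <- a$attributes[[1]]
      if (!all(c("category_id", "matched_form") %in% names(at)))
        stop_litmine("lexical annotation ", ann_label(a),
                     " must carry category_id and matched_form attributes",
                     class = "litmine_validation_error")
      cov <- substr(doc$sofa, a$begin + 1L, a$end)
      cs <- identical(at[["case_sensitive"]], "true")
      if (!form_matches_text(at[["matched_form"]], cov, cs))
        stop_litmine("lexical annotation ", ann_label(a),
                     ": matched_form '", at[["matched_form"]],
                     "' does not match covered text '", cov, "'",
                     class = "litmine_validation_error")
    }
  }
  invisible(TRUE)
}

check_no_overlap <- function(anns, layer) {
  sub <- anns[anns$layer == layer, , drop = FALSE]
  if (nrow(sub) < 2L) return(invisible(TRUE))
  sub <- sub[order(sub$begin, sub$end), , drop = FALSE]
  bad <- which(sub$begin[-1L] < sub$end[-nrow(sub)])
  if (length(bad))
    stop_litmine("overlapping ", layer, " annotations: ",
                 ann_label(sub[bad[1L], ]), " and ",
                 ann_label(sub[bad[1L] + 1L, ]),
                 class = "litmine_validation_error")
  invisible(TRUE)
}

sort_annotations <- function(anns) {
  anns[order(anns$begin, anns$end, anns$layer, anns$ann_id), , drop = FALSE]
}

next_ann_ids <- function(doc, n) {
  existing <- doc$annotations$ann_id
  k <- 0L
  if (length(existing)) {
    nums <- suppressWarnings(as.integer(sub("^a", "", existing)))
    if (any(!is.na(nums))) k <- max(nums, na.rm = TRUE)
  }
  sprintf("a%06d", k + seq_len(n))
}

#' Append annotations to a document
#'
#' Validates each annotation against the document (range, layer, lexical
#' attribute contract) and the layer invariants (sentence and token
#' annotations must be pairwise non-overlapping), then appends. The SofA
#' is never modified; existing annotations are untouched.
#'
#' @param doc a `litdoc`.
#' @param anns an annotation data frame from [annotations()].
#' @return the document with the annotations appended, sorted by
#'   `(begin, end, layer)`.
#' @export
add_annotations <- function(doc, anns) {
  stopifnot(inherits(doc, "litdoc"))
  if (!is.data.frame(anns))
    stop_litmine("anns must be an annotation data frame",
                 class = "litmine_validation_error")
  if (!nrow(anns)) return(doc)
  validate_annotation_rows(doc, anns)
  need_id <- is.na(anns$ann_id)
  if (any(need_id)) anns$ann_id[need_id] <- next_ann_ids(doc, sum(need_id))
  if (anyDuplicated(c(doc$annotations$ann_id, anns$ann_id)))
    stop_litmine("duplicate annotation ids",
                 class = "litmine_validation_error")
  merged <- rbind(doc$annotations, anns)
  for (layer in c("sentence", "token")) check_no_overlap(merged, layer)
  doc$annotations <- sort_annotations(merged)
  rownames(doc$annotations) <- NULL
  doc
}

#' Layer accessor
#'
#' @param doc a `litdoc`.
#' @param layer layer name.
#' @return the sub-table of annotations on that layer, sorted by begin.
#' @export
doc_layer <- function(doc, layer) {
  sub <- doc$annotations[doc$annotations$layer == layer, , drop = FALSE]
  sub[order(sub$begin, sub$end), , drop = FALSE]
}

#' Remove a layer (used e.g. to re-run lexical annotation)
#' @inheritParams doc_layer
#' @return the document without annotations on that layer.
#' @export
clear_layer <- function(doc, layer) {
  doc$annotations <- doc$annotations[doc$annotations$layer != layer, ,
                                     drop = FALSE]
  rownames(doc$annotations) <- NULL
  doc
}

#' Text covered by an annotation
#'
#' @param doc a `litdoc`.
#' @param ann a one-row annotation data frame belonging to `doc`, or an
#'   `ann_id` string.
#' @return the SofA slice `[begin, end)`.
#' @export
covered_text <- function(doc, ann) {
  stopifnot(inherits(doc, "litdoc"))
  if (is.character(ann)) {
    idx <- match(ann, doc$annotations$ann_id)
    if (is.na(idx))
      stop_litmine("annotation '", ann, "' does not belong to document ",
                   doc$doc_id, class = "litmine_foreign_annotation")
    ann <- doc$annotations[idx, ]
  } else {
    stopifnot(is.data.frame(ann), nrow(ann) == 1L)
    own <- doc$annotations
    hit <- own$ann_id == ann$ann_id & own$layer == ann$layer &
      own$begin == ann$begin & own$end == ann$end
    if (!any(hit))
      stop_litmine("annotation ", ann_label(ann),
                   " does not belong to document ", doc$doc_id,
                   class = "litmine_foreign_annotation")
  }
  substr(doc$sofa, ann$begin + 1L, ann$end)
}

#' Validate a document's structural invariants
#'
#' Checks per-annotation validity plus the cross-layer contracts: sentence
#' and token layers non-overlapping and sorted, each token inside exactly
#' one sentence, and each lexical annotation aligned with whole tokens
#' (when a token layer is present).
#'
#' @param doc a `litdoc`.
#' @return `TRUE` invisibly; errors with a diagnostic otherwise.
#' @export
validate_document <- function(doc) {
  stopifnot(inherits(doc, "litdoc"))
  validate_annotation_rows(doc, doc$annotations)
  check_no_overlap(doc$annotations, "sentence")
  check_no_overlap(doc$annotations, "token")
  toks <- doc_layer(doc, "token")
  sents <- doc_layer(doc, "sentence")
  if (nrow(toks) && nrow(sents)) {
    # each token entirely within exactly one sentence
    hit <- vapply(seq_len(nrow(toks)), function(i) {
      sum(sents$begin <= toks$begin[i] & sents$end >= toks$end[i])
    }, integer(1))
    if (any(hit != 1L))
      stop_litmine("token not contained in exactly one sentence: ",
                   ann_label(toks[which(hit != 1L)[1L], ]),
                   class = "litmine_validation_error")
  }
  lex <- doc_layer(doc, "lexical")
  if (nrow(lex) && nrow(toks)) {
    ok <- vapply(seq_len(nrow(lex)), function(i) {
      any(toks$begin == lex$begin[i]) && any(toks$end == lex$end[i])
    }, logical(1))
    if (any(!ok))
      stop_litmine("lexical annotation not aligned with whole tokens: ",
                   ann_label(lex[which(!ok)[1L], ]),
                   class = "litmine_validation_error")
  }
  if (doc$stage >= 1L && !nrow(toks))
    stop_litmine("stage >= 1 document must carry a token layer",
                 class = "litmine_validation_error")
  invisible(TRUE)
}

# ---- serialization ---------------------------------------------------------

bib_to_list <- function(b) {
  list(accession = b$accession, title = b$title,
       authors = as.list(b$authors), journal = b$journal,
       year = if (is.na(b$year)) NULL else b$year,
       article_type = b$article_type, subjects = as.list(b$subjects),
       abstract = b$abstract)
}

bib_from_list <- function(l) {
  bibliography(accession = l$accession, title = l$title %||% "",
               authors = as_chr(l$authors %||% list()),
               journal = l$journal %||% "",
               year = if (is.null(l$year)) NA_integer_ else l$year,
               article_type = l$article_type %||% "",
               subjects = as_chr(l$subjects %||% list()),
               abstract = l$abstract %||% "")
}

doc_to_list <- function(doc) {
  anns <- sort_annotations(doc$annotations)
  ann_list <- lapply(seq_len(nrow(anns)), function(i) {
    at <- anns$attributes[[i]]
    if (length(at)) at <- at[order(names(at))]
    list(ann_id = anns$ann_id[i], layer = anns$layer[i],
         begin = anns$begin[i], end = anns$end[i],
         attributes = if (length(at)) as.list(at)
                      else structure(list(), names = character()))
  })
  list(doc_id = doc$doc_id, sofa = doc$sofa,
       bibliography = bib_to_list(doc$bibliography),
       annotations = ann_list,
       subcorpora = as.list(sort(unique(doc$subcorpora))),
       stage = doc$stage)
}

doc_from_list <- function(l) {
  doc <- create_document(l$sofa, bib_from_list(l$bibliography))
  n <- length(l$annotations)
  if (n) {
    anns <- annotations(
      layer = vapply(l$annotations, `[[`, "", "layer"),
      begin = vapply(l$annotations, function(a) as.integer(a$begin),
                     integer(1)),
      end = vapply(l$annotations, function(a) as.integer(a$end), integer(1)),
      attributes = lapply(l$annotations, function(a) {
        at <- a$attributes
        if (!length(at)) character() else
          structure(as_chr(at), names = names(at))
      }),
      ann_id = vapply(l$annotations, `[[`, "", "ann_id"))
    doc <- add_annotations(doc, anns)
  }
  doc$subcorpora <- as_chr(l$subcorpora %||% list())
  doc$stage <- as.integer(l$stage %||% 0L)
  doc
}

#' Write / read a single document JSON file
#'
#' The on-disk format is one UTF-8 JSON object per article:
#' `{doc_id, sofa, bibliography{...}, annotations[...], subcorpora[], stage}`
#' with annotations sorted by `(begin, end, layer)`. A store round-trip
#' reproduces a byte-identical SofA and an equal annotation set.
#'
#' @param doc a `litdoc`.
#' @param path file path.
#' @return `write_document`: the path, invisibly; `read_document`: the
#'   document.
#' @export
write_document <- function(doc, path) {
  json_write_canonical(doc_to_list(doc), path)
}

#' @rdname write_document
#' @export
read_document <- function(path) {
  l <- tryCatch(json_read(path), error = function(e)
    stop_litmine("cannot parse document file ", path, ": ",
                 conditionMessage(e), class = "litmine_parse_error"))
  doc_from_list(l)
}

# ---- corpus store ----------------------------------------------------------

safe_filename <- function(doc_id) {
  paste0(gsub("[^A-Za-z0-9._-]", "_", doc_id), ".json")
}

#' Open (or create) a file-backed corpus store
#'
#' A store is a directory with a `manifest.json` (doc ids, completed
#' pipeline stage, sub-corpus labels, file names) and one JSON document
#' per article under `docs/`.
#'
#' @param root directory path.
#' @return an object of class `corpus_store`.
#' @export
corpus_store <- function(root) {
  dir.create(file.path(root, "docs"), recursive = TRUE, showWarnings = FALSE)
  mf <- file.path(root, "manifest.json")
  if (!file.exists(mf))
    json_write_canonical(list(docs = structure(list(), names = character())),
                         mf)
  structure(list(root = root), class = "corpus_store")
}

store_manifest <- function(store) {
  json_read(file.path(store$root, "manifest.json"))
}

write_manifest <- function(store, manifest) {
  ids <- names(manifest$docs)
  manifest$docs <- manifest$docs[order(ids)]
  if (!length(manifest$docs))
    manifest$docs <- structure(list(), names = character())
  json_write_canonical(manifest, file.path(store$root, "manifest.json"))
}

#' Save / load documents in a corpus store
#'
#' @param store a [corpus_store()].
#' @param doc a `litdoc` (for `store_save`).
#' @param doc_id a document id (for `store_load`).
#' @return `store_save`: the store, invisibly. `store_load`: the document.
#'   `store_ids`: character vector of stored ids (sorted).
#' @export
store_save <- function(store, doc) {
  stopifnot(inherits(store, "corpus_store"), inherits(doc, "litdoc"))
  validate_document(doc)
  fn <- safe_filename(doc$doc_id)
  write_document(doc, file.path(store$root, "docs", fn))
  manifest <- store_manifest(store)
  manifest$docs[[doc$doc_id]] <-
    list(file = fn, stage = doc$stage,
         subcorpora = as.list(sort(unique(doc$subcorpora))))
  write_manifest(store, manifest)
  invisible(store)
}

#' @rdname store_save
#' @export
store_load <- function(store, doc_id) {
  manifest <- store_manifest(store)
  entry <- manifest$docs[[doc_id]]
  if (is.null(entry))
    stop_litmine("document '", doc_id, "' not found in store ",
                 store$root, class = "litmine_not_found")
  read_document(file.path(store$root, "docs", entry$file))
}

#' @rdname store_save
#' @export
store_ids <- function(store) {
  sort(names(store_manifest(store)$docs))
}

#' @export
print.litdoc <- function(x, ...) {
  cat(sprintf("<litdoc %s> stage %d, %d chars, %d annotations, [%s]\n",
              x$doc_id, x$stage, nchr(x$sofa), nrow(x$annotations),
              paste(x$subcorpora, collapse = ", ")))
  invisible(x)
}

#' @export
print.corpus_store <- function(x, ...) {
  cat(sprintf("<corpus_store %s> %d documents\n", x$root,
              length(store_ids(x))))
  invisible(x)
}
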