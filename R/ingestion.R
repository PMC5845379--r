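#' @title Article ingestion: NXML / plain text to stage-1 documents
#'
#' @description The converter parses a JATS/NXML article (the PubMed
#' Central tagging style) or a plain-text file with sidecar metadata,
#' assembles the SofA (title, abstract, body paragraphs, figure/table
#' captions, in document order, separated by blank lines) and attaches
#' paragraph, section, sentence, token and image annotations plus the
#' bibliography.
#'
#' @name ingestion
NULL

#' Default sentence-boundary abbreviation exceptions
#'
#' A period following one of these strings (or a single capital letter, as
#' in genus abbreviations like "C. elegans") is never a sentence boundary.
#' @return character vector of abbreviations (each ending in ".").
#' @export
default_abbreviations <- function() {
  c("Fig.", "Figs.", "et al.", "e.g.", "i.e.", "vs.", "ca.")
}

#' Word tokenization
#'
#' Tokens are maximal runs of Unicode letters/digits in which the
#' characters `-`, `.`, `/`, `_` and `'` are token-internal iff flanked on
#' both sides by a letter or digit (so "zyg-1" is one token, "end. Next"
#' yields "end" and "Next"). Punctuation and whitespace produce no tokens.
#'
#' @param text a string.
#' @return data frame with columns `begin`, `end` (0-based, half-open code
#'   point offsets), non-overlapping and sorted; empty for empty text.
#' @export
tokenize <- function(text) {
  if (!is_string(text) || !nzchar(text))
    return(data.frame(begin = integer(), end = integer()))
  text <- enc2utf8(text)
  m <- gregexpr("[\\p{L}\\p{N}]+(?:[-./_'][\\p{L}\\p{N}]+)*", text,
                perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(begin = integer(), end = integer()))
  begin <- as.integer(m) - 1L
  data.frame(begin = begin, end = begin + attr(m, "match.length"))
}

token_texts <- function(text, tokens) {
  if (!nrow(tokens)) return(character())
  substring(text, tokens$begin + 1L, tokens$end)
}

# is a '.' at 1-based position pos an abbreviation (no boundary)?
is_abbrev_dot <- function(text, pos, abbreviations) {
  tail_start <- max(1L, pos - 14L)
  tail <- substr(text, tail_start, pos)
  for (ab in abbreviations) {
    pat <- paste0("(^|[\\s(\\[])", gsub("([.\\\\])", "\\\\\\1", ab), "$")
    if (grepl(pat, tail, perl = TRUE)) return(TRUE)
  }
  # single-capital genus abbreviation: "C. elegans"
  grepl("(^|[\\s(\\[])\\p{Lu}\\.$", tail, perl = TRUE)
}

#' Sentence splitting
#'
#' Boundaries occur after `.`, `!` or `?` followed by whitespace and an
#' uppercase letter or digit, except when the period terminates an entry
#' of the abbreviation exception list (or a single-capital genus
#' abbreviation such as "C." in "C. elegans"). Every token lies in exactly
#' one sentence; sentence spans are trimmed of surrounding whitespace.
#'
#' @param text a paragraph string.
#' @param tokens token spans from [tokenize()] on the same text.
#' @param abbreviations abbreviation exception list; see
#'   [default_abbreviations()].
#' @return data frame with columns `begin`, `end` (0-based, half-open).
#' @export
split_sentences <- function(text, tokens = tokenize(text),
                            abbreviations = default_abbreviations()) {
  if (!nrow(tokens)) return(data.frame(begin = integer(), end = integer()))
  text <- enc2utf8(text)
  m <- gregexpr("[.!?](?=\\s+[\\p{Lu}\\p{N}])", text, perl = TRUE)[[1]]
  bounds <- integer()
  if (m[1] != -1L) {
    for (pos in as.integer(m)) {
      ch <- substr(text, pos, pos)
      if (ch == "." && is_abbrev_dot(text, pos, abbreviations)) next
      bounds <- c(bounds, pos)   # boundary AFTER this character
    }
  }
  seg_start <- c(1L, bounds + 1L)
  seg_end <- c(bounds, nchr(text))
  out_begin <- integer(); out_end <- integer()
  for (k in seq_along(seg_start)) {
    seg <- substr(text, seg_start[k], seg_end[k])
    # tokens whose begin falls inside this segment
    in_seg <- tokens$begin >= seg_start[k] - 1L & tokens$begin < seg_end[k]
    if (!any(in_seg)) {
      # token-less tail (e.g. stray punctuation): merge into previous
      if (length(out_end)) {
        tail_txt <- sub("\\s+$", "", seg, perl = TRUE)
        extra <- nchr(tail_txt)
        if (extra > 0L) out_end[length(out_end)] <- seg_start[k] - 1L + extra
      }
      next
    }
    lead <- nchr(sub("^(\\s*).*$", "\\1", seg, perl = TRUE))
    trail <- nchr(seg) - nchr(sub("\\s+$", "", seg, perl = TRUE))
    out_begin <- c(out_begin, seg_start[k] - 1L + lead)
    out_end <- c(out_end, seg_end[k] - trail)
  }
  data.frame(begin = out_begin, end = out_end)
}

# ---- NXML parsing ----------------------------------------------------------

xml_text_squish <- function(node) {
  if (length(node) == 0) return("")
  squish(xml2::xml_text(node))
}

#' Parse a JATS/NXML article
#'
#' Extracts front matter (title, journal, year, authors, article type,
#' subjects, abstract, accession), body blocks as ordered
#' (section label, paragraph text) pairs, and figure/table captions.
#' Entity references and inline markup (italics, xrefs) are flattened to
#' text; missing optional fields become empty/unknown. Accession
#' preference order: pmid, then pmc, then doi, then the filename stem.
#'
#' @param x path to an `.nxml`/`.xml` file, or a string of XML.
#' @param fallback_id accession used when the article carries no id
#'   (defaults to the filename stem).
#' @return an object of class `nxml_article`.
#' @export
parse_nxml <- function(x, fallback_id = NULL) {
  if (is_string(x) && file.exists(x) && is.null(fallback_id))
    fallback_id <- sub("\\.[^.]*$", "", basename(x))
  xml <- tryCatch(xml2::read_xml(x),
                  error = function(e)
                    stop_litmine("malformed XML: ", conditionMessage(e),
                                 class = "litmine_parse_error"))
  root <- xml2::xml_root(xml)
  meta <- xml2::xml_find_first(xml, ".//front//article-meta")
  title <- xml_text_squish(xml2::xml_find_first(
    xml, ".//front//article-meta//article-title"))
  journal <- xml_text_squish(xml2::xml_find_first(
    xml, ".//front//journal-meta//journal-title"))
  year_txt <- xml_text_squish(xml2::xml_find_first(
    xml, ".//front//article-meta//pub-date/year"))
  year <- suppressWarnings(as.integer(year_txt))
  authors <- vapply(
    xml2::xml_find_all(
      xml, ".//front//article-meta//contrib[@contrib-type='author']/name"),
    function(nm) {
      given <- xml_text_squish(xml2::xml_find_first(nm, "./given-names"))
      sur <- xml_text_squish(xml2::xml_find_first(nm, "./surname"))
      squish(paste(given, sur))
    }, character(1))
  subjects <- vapply(
    xml2::xml_find_all(xml,
      ".//front//article-meta//article-categories//subject"),
    function(s) xml_text_squish(s), character(1))
  abstract <- xml_text_squish(xml2::xml_find_first(
    xml, ".//front//article-meta/abstract"))
  article_type <- xml2::xml_attr(root, "article-type")
  if (is.na(article_type)) article_type <- ""
  ids <- xml2::xml_find_all(xml, ".//front//article-meta/article-id")
  id_types <- xml2::xml_attr(ids, "pub-id-type")
  id_vals <- vapply(ids, xml_text_squish, character(1))
  accession <- NA_character_
  for (pref in c("pmid", "pmc", "doi")) {
    hit <- which(id_types == pref)
    if (length(hit)) { accession <- id_vals[hit[1L]]; break }
  }
  if (is.na(accession) || !nzchar(accession))
    accession <- fallback_id %||% NA_character_
  if ((is.na(accession) || !nzchar(accession)) && !nzchar(title))
    stop_litmine("document unidentifiable: no article-title and no accession",
                 class = "litmine_parse_error")
  if (is.na(accession) || !nzchar(accession))
    accession <- gsub("[^A-Za-z0-9._-]+", "_", substr(title, 1, 40))

  # body paragraphs outside figures/tables, with nearest section label
  ps <- xml2::xml_find_all(
    xml, ".//body//p[not(ancestor::fig) and not(ancestor::table-wrap)]")
  blocks <- lapply(ps, function(p) {
    txt <- xml_text_squish(p)
    if (!nzchar(txt)) return(NULL)
    sec <- xml2::xml_find_first(p, "./ancestor::sec[1]")
    label <- if (length(sec) == 0 || inherits(sec, "xml_missing")) "body"
             else xml_text_squish(xml2::xml_find_first(sec, "./title"))
    if (!nzchar(label)) label <- "body"
    list(section = label, text = txt)
  })
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]

  figs <- xml2::xml_find_all(xml, ".//body//fig | .//body//table-wrap")
  figures <- lapply(figs, function(f) {
    cap <- xml_text_squish(xml2::xml_find_first(f, ".//caption"))
    lab <- xml_text_squish(xml2::xml_find_first(f, "./label"))
    cap_full <- squish(paste(lab, cap))
    if (!nzchar(cap_full)) return(NULL)
    g <- xml2::xml_find_first(f, ".//graphic")
    href <- ""
    if (length(g) > 0 && !inherits(g, "xml_missing")) {
      at <- xml2::xml_attrs(g)
      hit <- grepl("(^|:)href$", names(at))
      if (any(hit)) href <- unname(at[hit][1L])
    }
    id <- xml2::xml_attr(f, "id")
    list(id = if (is.na(id)) "" else id, caption = cap_full, href = href)
  })
  figures <- figures[!vapply(figures, is.null, logical(1))]

  structure(list(title = title, journal = journal, year = year,
                 authors = authors, article_type = article_type,
                 subjects = subjects, abstract = abstract,
                 accession = accession, blocks = blocks,
                 figures = figures),
            class = "nxml_article")
}

#' Convert a parsed article (or plain text) to a stage-1 document
#'
#' The SofA is the concatenation of title, abstract, body paragraphs and
#' figure/table captions in document order, separated by blank lines.
#' Paragraph annotations cover each block; section annotations cover runs
#' of blocks sharing a label; image annotations cover caption blocks and
#' carry the graphic reference; token and sentence layers are attached.
#'
#' @param x an `nxml_article` from [parse_nxml()], or a plain-text string.
#' @param bib a [bibliography()] (required for plain text; derived from
#'   front matter for NXML).
#' @param abbreviations sentence-splitter exception list.
#' @return a stage-1 `litdoc`.
#' @export
convert_article <- function(x, bib = NULL,
                            abbreviations = default_abbreviations()) {
  if (inherits(x, "nxml_article")) {
    bib <- bibliography(accession = x$accession, title = x$title,
                        authors = x$authors, journal = x$journal,
                        year = if (length(x$year) && !is.na(x$year)) x$year
                               else NA_integer_,
                        article_type = x$article_type,
                        subjects = x$subjects, abstract = x$abstract)
    blocks <- list()
    imgs <- list()
    if (nzchar(x$title))
      blocks[[length(blocks) + 1L]] <- list(section = "title",
                                            text = x$title)
    if (nzchar(x$abstract))
      blocks[[length(blocks) + 1L]] <- list(section = "abstract",
                                            text = x$abstract)
    for (b in x$blocks) blocks[[length(blocks) + 1L]] <- b
    for (f in x$figures) {
      blocks[[length(blocks) + 1L]] <- list(section = "figures",
                                            text = f$caption,
                                            image = f)
    }
  } else {
    if (!is_string(x)) stop_litmine("x must be an nxml_article or a string",
                                    class = "litmine_invalid_input")
    if (is.null(bib)) stop_litmine("plain-text conversion needs a bibliography",
                                   class = "litmine_invalid_input")
    paras <- strsplit(x, "\\n\\s*\\n", perl = TRUE)[[1]]
    paras <- vapply(paras, squish, character(1), USE.NAMES = FALSE)
    paras <- paras[nzchar(paras)]
    if (!length(paras)) stop_litmine("empty document text",
                                     class = "litmine_invalid_input")
    blocks <- lapply(paras, function(p) list(section = "body", text = p))
  }
  texts <- vapply(blocks, `[[`, "", "text")
  sofa <- paste(texts, collapse = "\n\n")
  doc <- create_document(sofa, bib)

  # block offsets
  lens <- nchr(texts)
  starts <- cumsum(c(0L, (lens + 2L)[-length(lens)]))  # "\n\n" separators
  ends <- starts + lens

  anns <- list()
  anns[[length(anns) + 1L]] <-
    annotations(layer = rep("paragraph", length(blocks)),
                begin = starts, end = ends)
  # section annotations: runs of consecutive blocks with equal labels
  labels <- vapply(blocks, `[[`, "", "section")
  run_id <- cumsum(c(TRUE, labels[-1L] != labels[-length(labels)]))
  for (r in unique(run_id)) {
    i <- which(run_id == r)
    anns[[length(anns) + 1L]] <-
      annotation("section", starts[min(i)], ends[max(i)],
                 c(label = labels[i[1L]]))
  }
  # image annotations on caption blocks
  for (k in seq_along(blocks)) {
    img <- blocks[[k]]$image
    if (!is.null(img))
      anns[[length(anns) + 1L]] <-
        annotation("image", starts[k], ends[k],
                   c(graphic = img$href, fig_id = img$id))
  }
  # tokens over the whole SofA (blank lines break tokens anyway)
  toks <- tokenize(sofa)
  if (nrow(toks))
    anns[[length(anns) + 1L]] <-
      annotations(layer = rep("token", nrow(toks)),
                  begin = toks$begin, end = toks$end)
  # sentences per paragraph block
  for (k in seq_along(blocks)) {
    btoks <- toks[toks$begin >= starts[k] & toks$end <= ends[k], ,
                  drop = FALSE]
    btoks$begin <- btoks$begin - starts[k]
    btoks$end <- btoks$end - starts[k]
    sents <- split_sentences(texts[k], btoks, abbreviations)
    if (nrow(sents))
      anns[[length(anns) + 1L]] <-
        annotations(layer = rep("sentence", nrow(sents)),
                    begin = sents$begin + starts[k],
                    end = sents$end + starts[k])
  }
  doc <- add_annotations(doc, do.call(rbind, anns))
  doc$stage <- 1L
  validate_document(doc)
  doc
}

#' Ingest a directory of articles into a corpus store
#'
#' NXML files (`.nxml`/`.xml`) are parsed with [parse_nxml()]; plain-text
#' files (`.txt`) require a JSON sidecar `<name>.json` with at least an
#' `accession` (or the filename stem is used) and optional
#' title/journal/year/authors/subjects.
#'
#' @param in_dir input directory.
#' @param store a [corpus_store()].
#' @param format `"nxml"` or `"txt"`.
#' @param abbreviations sentence-splitter exception list.
#' @param force reprocess documents already in the store.
#' @return character vector of ingested doc ids.
#' @export
ingest_dir <- function(in_dir, store, format = c("nxml", "txt"),
                       abbreviations = default_abbreviations(),
                       force = FALSE) {
  format <- match.arg(format)
  patt <- if (format == "nxml") "\\.(nxml|xml)$" else "\\.txt$"
  files <- sort(list.files(in_dir, pattern = patt, full.names = TRUE))
  existing <- store_ids(store)
  done <- character()
  for (f in files) {
    if (format == "nxml") {
      art <- parse_nxml(f)
      if (!force && art$accession %in% existing) next
      doc <- convert_article(art, abbreviations = abbreviations)
    } else {
      sidecar <- sub("\\.txt$", ".json", f)
      meta <- if (file.exists(sidecar)) json_read(sidecar) else list()
      acc <- meta$accession %||% sub("\\.txt$", "", basename(f))
      if (!force && acc %in% existing) next
      bib <- bibliography(accession = acc, title = meta$title %||% "",
                          authors = as_chr(meta$authors %||% list()),
                          journal = meta$journal %||% "",
                          year = if (is.null(meta$year)) NA_integer_
                                 else meta$year,
                          subjects = as_chr(meta$subjects %||% list()))
      doc <- convert_article(paste(readLines(f, warn = FALSE),
                                   collapse = "\n"),
                             bib, abbreviations)
    }
    store_save(store, doc)
    done <- c(done, doc$doc_id)
  }
  done
}
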