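#' @title Deterministic synthetic fixtures: toy ontologies and corpora
#'
#' @description The fixture generators build small OBO ontologies and
#' NXML articles with category terms planted at known positions, so the
#' whole pipeline is testable with exact ground truth and no downloads.
#' Filler vocabulary and planted forms are drawn from disjoint alphabets
#' (filler words use only the letters a-h; term words start with "q" and
#' continue with letters n-z), and all term/synonym words are drawn
#' without replacement, so no planted form can occur by accident or
#' inside another: ground truth is exact rather than probabilistic.
#'
#' @name fixtures
NULL

#' Fixture specification
#'
#' @param seed integer seed; the same spec and seed give byte-identical
#'   outputs.
#' @param n_docs number of articles.
#' @param n_terms number of ontology terms.
#' @param depth_max maximum ontology depth (> 4 exercises deep-term
#'   folding).
#' @param synonyms_range min/max synonyms per term.
#' @param sentences_range min/max sentences per paragraph.
#' @param plants_range min/max planted term occurrences per document.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_docs = 20L, n_terms = 30L,
                         depth_max = 6L, synonyms_range = c(0L, 2L),
                         sentences_range = c(3L, 8L),
                         plants_range = c(1L, 5L)) {
  if (depth_max > n_terms)
    stop_litmine("contradictory fixture spec: depth_max > n_terms",
                 class = "litmine_invalid_input")
  structure(list(seed = as.integer(seed), n_docs = as.integer(n_docs),
                 n_terms = as.integer(n_terms),
                 depth_max = as.integer(depth_max),
                 synonyms_range = as.integer(synonyms_range),
                 sentences_range = as.integer(sentences_range),
                 plants_range = as.integer(plants_range)),
            class = "fixture_spec")
}

rint <- function(lo, hi) if (hi <= lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L

# unique words over a restricted alphabet, disjoint from filler words
term_word_pool <- function(n) {
  out <- character(0)
  while (length(out) < n) {
    w <- paste0("q", paste(sample(letters[14:26], rint(4L, 7L),
                                  replace = TRUE), collapse = ""))
    if (!w %in% out) out <- c(out, w)
  }
  out
}

filler_word <- function() {
  paste(sample(letters[1:8], rint(3L, 7L), replace = TRUE), collapse = "")
}

#' Generate a toy OBO ontology
#'
#' Emits a rooted `is_a` tree of `n_terms` non-obsolete terms (ids
#' `FX:0000001` ...; unique one- or two-word names; 0-2 synonyms per
#' term, some carrying a digit suffix so they are matched
#' case-sensitively) plus two obsolete stanzas, deterministic under the
#' spec seed.
#'
#' @param spec a [fixture_spec()].
#' @return list with `text` (OBO flat file), `terms` (data frame
#'   `term_id, name, parent, depth`), and `synonyms` (data frame
#'   `term_id, text`).
#' @export
generate_obo <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_terms
  # words for names and synonyms drawn without replacement globally
  pool <- term_word_pool(4L * n)
  used <- 0L
  take <- function(k) {
    w <- pool[(used + 1L):(used + k)]
    used <<- used + k
    w
  }
  ids <- sprintf("FX:%07d", seq_len(n))
  depth <- integer(n); depth[1L] <- 1L
  parent <- rep(NA_character_, n)
  name <- character(n)
  synonyms <- list()
  for (i in seq_len(n)) {
    name[i] <- paste(take(rint(1L, 2L)), collapse = " ")
    if (i > 1L) {
      cand <- which(depth[seq_len(i - 1L)] < spec$depth_max)
      p <- cand[rint(1L, length(cand))]
      parent[i] <- ids[p]
      depth[i] <- depth[p] + 1L
    }
    k <- rint(spec$synonyms_range[1L], spec$synonyms_range[2L])
    if (k > 0L) for (s in seq_len(k)) {
      syn <- paste(take(rint(1L, 2L)), collapse = " ")
      if (runif(1) < 0.3)  # digit suffix: case-sensitive form
        syn <- paste0(syn, "-", rint(1L, 9L))
      synonyms[[length(synonyms) + 1L]] <- c(ids[i], syn)
    }
  }
  syn_df <- if (length(synonyms))
    data.frame(term_id = vapply(synonyms, `[`, "", 1L),
               text = vapply(synonyms, `[`, "", 2L),
               stringsAsFactors = FALSE)
  else data.frame(term_id = character(), text = character())
  out <- c("format-version: 1.2", "")
  for (i in seq_len(n)) {
    out <- c(out, "[Term]", paste0("id: ", ids[i]),
             paste0("name: ", name[i]))
    for (s in syn_df$text[syn_df$term_id == ids[i]])
      out <- c(out, sprintf('synonym: "%s" EXACT []', s))
    if (!is.na(parent[i])) out <- c(out, paste0("is_a: ", parent[i]))
    out <- c(out, "")
  }
  # obsolete stanzas: excluded by the parser
  for (j in 1:2) {
    out <- c(out, "[Term]", sprintf("id: FX:%07d", n + j),
             paste0("name: ", paste(take(1L), collapse = " ")),
             "is_obsolete: true", "")
  }
  list(text = paste(out, collapse = "\n"),
       terms = data.frame(term_id = ids, name = name, parent = parent,
                          depth = depth, stringsAsFactors = FALSE),
       synonyms = syn_df)
}

#' Default sub-corpus rules
#'
#' The conventional regex rules over title/journal/subjects:
#' Genetics `[Gg]enet`, Genomics `[Gg]enom`, Medicine `[Mm]edicin`.
#' @return a [subcorpus_rules()] data frame.
#' @export
default_subcorpus_rules <- function() {
  subcorpus_rules(c("Genetics", "Genomics", "Medicine"),
                  c("[Gg]enet", "[Gg]enom", "[Mm]edicin"))
}

mangle_case <- function(x) {
  ch <- strsplit(x, "")[[1]]
  alpha <- grepl("[a-zA-Z]", ch)
  i <- which(alpha)[1L]
  ch[i] <- if (ch[i] %in% letters) toupper(ch[i]) else tolower(ch[i])
  paste(ch, collapse = "")
}

#' Generate an NXML fixture corpus with planted category terms
#'
#' Each article gets front matter (titles drawn from templates that
#' exercise the sub-corpus regexes, journal, year, authors, subjects), an
#' abstract and body paragraphs of filler sentences with lexicon surface
#' forms planted at recorded offsets, and (for some articles) a figure
#' caption. Some sentences carry "C. elegans" / "see Fig. 3" style
#' abbreviation patterns to exercise non-splitting. For case-sensitive
#' forms, case-mangled decoys are planted that must NOT be annotated.
#'
#' @param spec a [fixture_spec()].
#' @param forest the `category_forest` whose surface forms are planted.
#' @param out_dir directory receiving the `.nxml` files.
#' @param rules sub-corpus rules used to record expected labels.
#' @return ground truth: list with `files`, `front` (per-doc front-matter
#'   data frame), `plants` (data frame `doc_id, category_id, begin, end,
#'   surface_form`), `sentences` (data frame `doc_id, begin, end`),
#'   `subcorpora` (named list), and `sofa` (named character, the expected
#'   SofA per document).
#' @export
generate_corpus <- function(spec, forest, out_dir,
                            rules = default_subcorpus_rules()) {
  stopifnot(inherits(spec, "fixture_spec"),
            inherits(forest, "category_forest"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed + 1000L)
  lex_all <- do.call(rbind, lapply(names(forest$nodes), function(id) {
    lx <- forest$nodes[[id]]$lexicon
    if (!nrow(lx)) return(NULL)
    data.frame(category_id = id, surface_form = lx$surface_form,
               case_sensitive = lx$case_sensitive,
               stringsAsFactors = FALSE)
  }))
  if (is.null(lex_all) || !nrow(lex_all))
    stop_litmine("forest has no surface forms",
                 class = "litmine_invalid_input")

  titles <- c("Population genetics of %s", "Genomic analysis of %s",
              "Clinical medicine and the %s cohort",
              "Structural biology of %s", "Ecology and evolution of %s")
  journals <- c("Genes", "Genome Medicine", "Archives of Biology",
                "Journal of Integrative Studies")
  subject_pool <- c("Genetics", "Cell Biology", "Ecology", "Biochemistry")
  surnames <- c("Adler", "Baum", "Chen", "Diaz", "Ebert", "Fuchs")

  front_rows <- list(); plant_rows <- list(); sent_rows <- list()
  subc <- list(); sofas <- character(); files <- character()

  new_sentence <- function() {
    words <- vapply(seq_len(rint(4L, 9L)), function(i) filler_word(),
                    character(1))
    substr(words[1L], 1L, 1L) <- toupper(substr(words[1L], 1L, 1L))
    r <- runif(1)
    if (r < 0.15) {
      at <- rint(2L, length(words))
      words <- append(words, c("in", "C.", "elegans", "bodies"), after = at)
    } else if (r < 0.3) {
      at <- rint(2L, length(words))
      words <- append(words, c("see", "Fig.", "3", "here"), after = at)
    }
    words
  }

  for (d in seq_len(spec$n_docs)) {
    acc <- sprintf("FIX%04d", d)
    title <- sprintf(titles[rint(1L, length(titles))], filler_word())
    journal <- journals[rint(1L, length(journals))]
    year <- rint(1995L, 2020L)
    authors <- vapply(seq_len(rint(1L, 3L)), function(i)
      paste(c("Ada", "Ben", "Eva", "Kim")[rint(1L, 4L)],
            surnames[rint(1L, length(surnames))]), character(1))
    subjects <- sort(sample(subject_pool, rint(1L, 2L)))

    # blocks: abstract + 2 sections x 1-2 paragraphs (+ optional caption)
    mk_para <- function() lapply(seq_len(rint(spec$sentences_range[1L],
                                              spec$sentences_range[2L])),
                                 function(i) new_sentence())
    abstract_sents <- lapply(seq_len(rint(1L, 2L)), function(i)
      new_sentence())
    sec_labels <- c("Introduction", "Results")
    body <- lapply(sec_labels, function(lb)
      lapply(seq_len(rint(1L, 2L)), function(i) mk_para()))
    has_fig <- runif(1) < 0.5
    caption_sents <- if (has_fig) list(new_sentence()) else NULL

    # plant surface forms (and occasional case-mangled decoys)
    paras <- list(list(kind = "abstract", si = 0L, pj = 0L,
                       sents = abstract_sents))
    for (si in seq_along(body)) for (pj in seq_along(body[[si]]))
      paras[[length(paras) + 1L]] <- list(kind = "body", si = si, pj = pj,
                                          sents = body[[si]][[pj]])
    if (has_fig)
      paras[[length(paras) + 1L]] <- list(kind = "caption", si = 0L,
                                          pj = 0L, sents = caption_sents)
    n_plants <- rint(spec$plants_range[1L], spec$plants_range[2L])
    planted_forms <- character()
    for (p in seq_len(n_plants)) {
      row <- lex_all[rint(1L, nrow(lex_all)), ]
      pk <- rint(1L, length(paras))
      sk <- rint(1L, length(paras[[pk]]$sents))
      words <- paras[[pk]]$sents[[sk]]
      at <- rint(2L, length(words))
      insert <- row$surface_form
      if (row$case_sensitive && runif(1) < 0.3) {
        insert <- mangle_case(insert)   # decoy: must not be annotated
      } else {
        planted_forms <- c(planted_forms, row$surface_form)
      }
      paras[[pk]]$sents[[sk]] <- append(words, insert, after = at)
    }

    # assemble blocks exactly as the converter does
    sent_text <- function(words, terminal = ".")
      paste0(paste(words, collapse = " "), terminal)
    block_texts <- c(title,
                     paste(vapply(paras[[1L]]$sents, sent_text, ""),
                           collapse = " "))
    body_block_of <- function(kind) which(vapply(paras, `[[`, "", "kind")
                                          == kind)
    for (k in body_block_of("body"))
      block_texts <- c(block_texts,
                       paste(vapply(paras[[k]]$sents, sent_text, ""),
                             collapse = " "))
    for (k in body_block_of("caption"))
      block_texts <- c(block_texts,
                       paste(vapply(paras[[k]]$sents, sent_text, ""),
                             collapse = " "))
    sofa <- paste(block_texts, collapse = "\n\n")

    # ground-truth sentence spans from assembly arithmetic
    lens <- nchr(block_texts)
    starts <- cumsum(c(0L, (lens + 2L)[-length(lens)]))
    sent_rows[[length(sent_rows) + 1L]] <-
      data.frame(doc_id = acc, begin = starts[1L], end = starts[1L] +
                   lens[1L])  # title = one sentence
    blk <- 1L
    for (k in seq_along(paras)) {
      blk <- blk + 1L
      off <- starts[blk]
      for (s in paras[[k]]$sents) {
        st <- sent_text(s)
        sent_rows[[length(sent_rows) + 1L]] <-
          data.frame(doc_id = acc, begin = off, end = off + nchr(st))
        off <- off + nchr(st) + 1L
      }
    }

    # ground-truth plants located in the assembled SofA
    for (form in unique(planted_forms)) {
      cat_id <- lex_all$category_id[lex_all$surface_form == form][1L]
      m <- gregexpr(form, sofa, fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      for (pos in as.integer(m)) {
        before <- if (pos > 1L) substr(sofa, pos - 1L, pos - 1L) else " "
        after_i <- pos + nchr(form)
        after <- if (after_i <= nchr(sofa))
          substr(sofa, after_i, after_i) else " "
        if (grepl("[A-Za-z0-9]", before) || grepl("[A-Za-z0-9]", after))
          next
        plant_rows[[length(plant_rows) + 1L]] <-
          data.frame(doc_id = acc, category_id = cat_id,
                     begin = pos - 1L, end = pos - 1L + nchr(form),
                     surface_form = form, stringsAsFactors = FALSE)
      }
    }

    front_rows[[length(front_rows) + 1L]] <-
      data.frame(doc_id = acc, title = title, journal = journal,
                 year = year, authors = I(list(authors)),
                 subjects = I(list(subjects)),
                 abstract = block_texts[2L], stringsAsFactors = FALSE)
    hit <- vapply(seq_len(nrow(rules)), function(i)
      any(grepl(rules$pattern[i], c(title, journal, subjects),
                perl = TRUE)), logical(1))
    subc[[acc]] <- sort(rules$label[hit])
    sofas[acc] <- sofa

    # write NXML
    xml <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      sprintf('<article xmlns:xlink="http://www.w3.org/1999/xlink" article-type="research-article">'),
      "<front><journal-meta><journal-title-group>",
      sprintf("<journal-title>%s</journal-title>", journal),
      "</journal-title-group></journal-meta><article-meta>",
      sprintf('<article-id pub-id-type="pmid">%s</article-id>', acc),
      sprintf("<title-group><article-title>%s</article-title></title-group>",
              title),
      "<contrib-group>",
      vapply(authors, function(a) {
        parts <- strsplit(a, " ", fixed = TRUE)[[1]]
        sprintf(paste0('<contrib contrib-type="author"><name><surname>%s',
                       "</surname><given-names>%s</given-names></name>",
                       "</contrib>"),
                parts[2L], parts[1L])
      }, character(1)),
      "</contrib-group>",
      sprintf("<pub-date><year>%d</year></pub-date>", year),
      "<article-categories><subj-group>",
      vapply(subjects, function(s) sprintf("<subject>%s</subject>", s),
             character(1)),
      "</subj-group></article-categories>",
      sprintf("<abstract><p>%s</p></abstract>", block_texts[2L]),
      "</article-meta></front><body>")
    bt <- 2L
    for (si in seq_along(sec_labels)) {
      n_par <- sum(vapply(paras, function(p)
        p$kind == "body" && p$si == si, logical(1)))
      xml <- c(xml, sprintf("<sec><title>%s</title>", sec_labels[si]))
      for (pj in seq_len(n_par)) {
        bt <- bt + 1L
        xml <- c(xml, sprintf("<p>%s</p>", block_texts[bt]))
      }
      xml <- c(xml, "</sec>")
    }
    if (has_fig) {
      bt <- bt + 1L
      xml <- c(xml, sprintf(paste0('<fig id="f1"><caption><p>%s</p>',
                                   '</caption><graphic xlink:href=',
                                   '"f1.jpg"/></fig>'), block_texts[bt]))
    }
    xml <- c(xml, "</body></article>")
    fn <- file.path(out_dir, paste0(acc, ".nxml"))
    writeLines(xml, fn, useBytes = TRUE)
    files <- c(files, fn)
  }

  list(files = files,
       front = do.call(rbind, front_rows),
       plants = if (length(plant_rows)) do.call(rbind, plant_rows)
                else data.frame(doc_id = character(),
                                category_id = character(),
                                begin = integer(), end = integer(),
                                surface_form = character()),
       sentences = do.call(rbind, sent_rows),
       subcorpora = subc, sofa = sofas)
}
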