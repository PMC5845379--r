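#' @title Processing pipeline: ingest, compile, annotate, index
#'
#' @description The batch pipeline wires the processing stages together:
#' stage 1 converts source articles into standoff documents, stage 2 runs
#' the lexical annotator and sub-corpus classifier, and indexing builds
#' the searchable inverted index from all stage-2 documents. Stage
#' tracking lives in the corpus-store manifest, so re-runs are idempotent
#' and skip up-to-date documents unless forced.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param store path to the corpus store directory.
#' @param in_dir input article directory (for the ingest step).
#' @param in_format `"nxml"` or `"txt"`.
#' @param obo path to an OBO file (for the compile step).
#' @param roots root term ids for the category forest.
#' @param wordlists named list of word-list line vectors (optional extra
#'   categories).
#' @param forest_file path where the compiled forest is stored (JSON).
#' @param rules_file path to sub-corpus rules JSON (`NULL` for the
#'   defaults).
#' @param index_dir directory receiving the index file.
#' @param max_depth category forest depth bound.
#' @param abbreviations sentence-splitter exception list.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(store, in_dir = NULL, in_format = "nxml",
                            obo = NULL, roots = NULL, wordlists = list(),
                            forest_file = file.path(store, "forest.json"),
                            rules_file = NULL,
                            index_dir = file.path(store, "index"),
                            max_depth = 4L,
                            abbreviations = default_abbreviations()) {
  structure(list(store = store, in_dir = in_dir, in_format = in_format,
                 obo = obo, roots = roots, wordlists = wordlists,
                 forest_file = forest_file, rules_file = rules_file,
                 index_dir = index_dir, max_depth = max_depth,
                 abbreviations = abbreviations),
            class = "pipeline_config")
}

#' Run pipeline steps
#'
#' Steps (any subset of `ingest`, `compile`, `annotate`, `index`) are
#' executed in stage order. `annotate` requires stage-1 documents in the
#' store and a compiled forest; `index` requires stage-2 documents.
#' Without `force`, documents already at the target stage are skipped.
#'
#' @param config a [pipeline_config()].
#' @param steps character vector of steps.
#' @param force reprocess up-to-date documents.
#' @param quiet suppress the per-step log lines on stderr.
#' @return a status report: named list of per-step counts and warnings.
#' @export
run_pipeline <- function(config,
                         steps = c("ingest", "compile", "annotate",
                                   "index"),
                         force = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  bad <- setdiff(steps, c("ingest", "compile", "annotate", "index"))
  if (length(bad))
    stop_litmine("unknown pipeline step(s): ", paste(bad, collapse = ", "))
  steps <- intersect(c("ingest", "compile", "annotate", "index"), steps)
  store <- corpus_store(config$store)
  report <- list()
  log <- function(step, msg) {
    if (!quiet) message(sprintf("[litmine] %s: %s", step, msg))
  }

  if ("ingest" %in% steps) {
    if (is.null(config$in_dir))
      stop_litmine("ingest step needs config$in_dir")
    done <- ingest_dir(config$in_dir, store, config$in_format,
                       config$abbreviations, force = force)
    report$ingest <- list(processed = length(done))
    log("ingest", sprintf("%d document(s) converted", length(done)))
  }

  if ("compile" %in% steps) {
    forests <- list()
    if (!is.null(config$obo)) {
      terms <- parse_obo(config$obo)
      roots <- config$roots
      if (is.null(roots)) {
        ids <- vapply(terms, `[[`, "", "term_id")
        has_parent <- vapply(terms, function(t)
          any(t$parents %in% ids), logical(1))
        roots <- ids[!has_parent]
      }
      forests[[length(forests) + 1L]] <-
        build_category_forest(terms, roots, config$max_depth)
    }
    for (nm in names(config$wordlists))
      forests[[length(forests) + 1L]] <-
        category_from_termlist(nm, config$wordlists[[nm]])
    if (!length(forests))
      stop_litmine("compile step needs config$obo and/or config$wordlists")
    forest <- do.call(merge_forests, forests)
    forest_save(forest, config$forest_file)
    report$compile <- list(categories = length(forest$nodes))
    log("compile", sprintf("%d categories compiled", length(forest$nodes)))
  }

  if ("annotate" %in% steps) {
    if (!file.exists(config$forest_file))
      stop_litmine("annotate step requires a compiled forest ",
                   "(run the compile step first)")
    forest <- forest_load(config$forest_file)
    tree <- build_lexicon_tree(forest)
    rules <- if (is.null(config$rules_file)) default_subcorpus_rules()
             else read_subcorpus_rules(config$rules_file)
    manifest <- store_manifest(store)
    ids <- sort(names(manifest$docs))
    stage1 <- ids[vapply(ids, function(i)
      (manifest$docs[[i]]$stage %||% 0L) >= 1L, logical(1))]
    if (!length(stage1))
      stop_litmine("no stage-1 documents in store; run the ingest step ",
                   "first", class = "litmine_precondition_error")
    todo <- if (force) stage1 else
      stage1[vapply(stage1, function(i)
        (manifest$docs[[i]]$stage %||% 0L) < 2L, logical(1))]
    for (id in todo) {
      doc <- store_load(store, id)
      doc <- annotate_document(doc, tree)
      doc$subcorpora <- classify_subcorpus(doc, rules)
      store_save(store, doc)
    }
    report$annotate <- list(processed = length(todo),
                            skipped = length(stage1) - length(todo))
    log("annotate", sprintf("%d document(s) annotated, %d up to date",
                            length(todo), length(stage1) - length(todo)))
  }

  if ("index" %in% steps) {
    manifest <- store_manifest(store)
    ids <- sort(names(manifest$docs))
    stage2 <- ids[vapply(ids, function(i)
      (manifest$docs[[i]]$stage %||% 0L) >= 2L, logical(1))]
    if (!length(stage2))
      stop_litmine("no stage-2 documents in store; run the annotate step ",
                   "first", class = "litmine_precondition_error")
    idx <- build_index(lapply(stage2, function(i) store_load(store, i)))
    dir.create(config$index_dir, recursive = TRUE, showWarnings = FALSE)
    index_save(idx, file.path(config$index_dir, "index.json"))
    report$index <- list(documents = idx$N)
    log("index", sprintf("%d document(s) indexed", idx$N))
  }

  invisible(report)
}
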