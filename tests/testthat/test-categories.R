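chain_obo <- function(n = 5L, prefix = "CH") {
  ids <- sprintf("%s:%d", prefix, seq_len(n))
  stanzas <- vapply(seq_len(n), function(i) paste0(
    "[Term]\nid: ", ids[i], "\nname: node", i, "\n",
    if (i > 1L) paste0("is_a: ", ids[i - 1L], "\n") else ""), character(1))
  list(text = paste(stanzas, collapse = "\n"), ids = ids)
}

test_that("OBO parsing extracts ids, names, synonyms, is_a, obsolete", {
  obo <- paste(
    "[Term]",
    "id: GO:0004674",
    "name: protein serine/threonine kinase activity",
    'synonym: "protein serine kinase activity" NARROW []',
    "is_a: GO:0016301 ! kinase activity",
    "",
    "[Term]",
    "id: GO:0000001",
    "name: gone now",
    "is_obsolete: true",
    "",
    "[Typedef]",
    "id: part_of",
    "name: part of",
    sep = "\n")
  terms <- parse_obo(obo)
  expect_length(terms, 1L)
  expect_identical(terms[[1]]$term_id, "GO:0004674")
  expect_identical(terms[[1]]$name,
                   "protein serine/threonine kinase activity")
  expect_identical(terms[[1]]$synonyms$text,
                   "protein serine kinase activity")
  expect_identical(terms[[1]]$synonyms$scope, "NARROW")
  expect_identical(terms[[1]]$parents, "GO:0016301")
  expect_warning(parse_obo("[Term]\nid: X:1\n\n[Term]\nid: X:2\nname: ok"),
                 "skipped 1 stanza")
})

test_that("depth-5 chain folds its deepest term into the depth-4 node", {
  ch <- chain_obo(5L)
  forest <- build_category_forest(parse_obo(ch$text), ch$ids[1])
  expect_setequal(names(forest$nodes), ch$ids[1:4])
  expect_identical(forest$nodes[[ch$ids[4]]]$depth, 4L)
  expect_setequal(forest$nodes[[ch$ids[4]]]$lexicon$surface_form,
                  c("node4", "node5"))
  # expansion of the root covers all five terms' names
  ex <- expand_with_children(forest, ch$ids[1])
  expect_setequal(ex$surface_form, paste0("node", 1:5))
  # single root, no children
  one <- build_category_forest(parse_obo(chain_obo(1L)$text), "CH:1")
  expect_identical(length(one$nodes), 1L)
  expect_identical(one$nodes[["CH:1"]]$depth, 1L)
})

test_that("every reachable term name lands in exactly one lexicon", {
  for (seed in 1:8) {
    spec <- fixture_spec(seed = seed, n_terms = 50L, depth_max = 6L)
    obo <- generate_obo(spec)
    terms <- parse_obo(obo$text)
    forest <- build_category_forest(terms, "FX:0000001", max_depth = 4L)
    counts <- vapply(obo$terms$name, function(nm)
      sum(vapply(forest$nodes, function(n)
        nm %in% n$lexicon$surface_form, logical(1))), integer(1))
    expect_true(all(counts == 1L))
    expect_lte(max(vapply(forest$nodes, `[[`, 1L, "depth")), 4L)
  }
})

test_that("cycles and unknown roots are rejected with diagnostics", {
  obo <- paste("[Term]\nid: C:1\nname: a\nis_a: C:2",
               "[Term]\nid: C:2\nname: b\nis_a: C:1", sep = "\n\n")
  expect_error(build_category_forest(parse_obo(obo), "C:1"), "cycle")
  expect_error(build_category_forest(parse_obo(chain_obo(2L)$text),
                                     "NOPE:1"), "unknown root")
})

test_that("multi-parent terms attach under the first-reached parent", {
  obo <- paste(
    "[Term]\nid: M:1\nname: root",
    "[Term]\nid: M:2\nname: pa\nis_a: M:1",
    "[Term]\nid: M:3\nname: pb\nis_a: M:1",
    "[Term]\nid: M:4\nname: shared\nis_a: M:3\nis_a: M:2",
    sep = "\n\n")
  forest <- build_category_forest(parse_obo(obo), "M:1")
  # breadth-first by term id: M:2 dequeued before M:3
  expect_identical(forest$nodes[["M:4"]]$parent, "M:2")
  expect_true("M:4" %in% forest$nodes[["M:2"]]$children)
  expect_false("M:4" %in% forest$nodes[["M:3"]]$children)
})

test_that("word lists compile like their OBO-stanza representation", {
  reset_category_ids()
  node <- category_from_termlist(
    "Enzymatic Activity",
    c("kinase activity\tphosphorylation activity", "protease activity"))
  lex <- node$nodes[[node$roots]]$lexicon
  expect_identical(nrow(lex), 3L)
  expect_setequal(lex$surface_form,
                  c("kinase activity", "phosphorylation activity",
                    "protease activity"))
  expect_match(node$roots, "^tpc:\\d{7}$")
  expect_error(category_from_termlist("X", character()),
               class = "litmine_invalid_input")
  # duplicates collapse
  dup <- category_from_termlist("d", c(rep("alpha beta", 10),
                                       paste("term", 1:90)))
  expect_identical(nrow(dup$nodes[[dup$roots]]$lexicon), 91L)

  # same processing pipeline: the OBO stanza route with depth 1 folds all
  # line terms into the root; its lexicon additionally holds the category
  # name itself (the root term's name)
  reset_category_ids()
  obo_txt <- termlist_to_obo(
    "Enzymatic Activity",
    c("kinase activity\tphosphorylation activity", "protease activity"))
  via_obo <- build_category_forest(parse_obo(obo_txt), "tpc:0000001",
                                   max_depth = 1L)
  expect_setequal(setdiff(via_obo$nodes[[1]]$lexicon$surface_form,
                          "Enzymatic Activity"),
                  lex$surface_form)
})

test_that("case policy marks digit- and mixed-case forms sensitive", {
  expect_identical(case_sensitive_form(c("ZYG-1", "DnaK", "kinase",
                                         "Kinase", "zyg-1", "abc")),
                   c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("expansion equals a brute-force union over descendant nodes", {
  set.seed(5)
  spec <- fixture_spec(seed = 5, n_terms = 40L, depth_max = 5L)
  forest <- build_category_forest(parse_obo(generate_obo(spec)$text),
                                  "FX:0000001")
  for (id in names(forest$nodes)) {
    ids <- c(id, forest_descendants_oracle(forest, id))
    want <- sort(unique(unlist(lapply(ids, function(i)
      forest$nodes[[i]]$lexicon$surface_form))))
    got <- sort(unique(expand_with_children(forest, id)$surface_form))
    expect_identical(got, want)
  }
  expect_error(expand_with_children(forest, "nope"),
               class = "litmine_not_found")
  # forest JSON round-trip
  p <- withr::local_tempfile(fileext = ".json")
  forest_save(forest, p)
  expect_equal(forest_load(p), forest)
})
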