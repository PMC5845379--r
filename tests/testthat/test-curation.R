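go_fixture <- function() {
  obo <- paste(
    "[Term]\nid: GO:0016301\nname: kinase activity",
    paste0("[Term]\nid: GO:0004674\n",
           "name: protein serine/threonine kinase activity\n",
           "is_a: GO:0016301"),
    sep = "\n\n")
  forest <- build_category_forest(parse_obo(obo), "GO:0016301")
  tree <- build_lexicon_tree(forest)
  doc <- text_doc(paste0(
    "ZYG-1 displays protein serine/threonine kinase activity in vivo. ",
    "Controls lacked any kinase activity. ",
    "Unrelated sentence about embryos."), accession = "PM1")
  list(forest = forest, doc = annotate_document(doc, tree))
}

test_that("schema validation reports duplicate positions and bad sources", {
  s <- form_schema("f", list(
    form_field("a", row = 0, col = 0),
    form_field("b", row = 0, col = 0),
    form_field("c", kind = "pulldown", row = 1, col = 0),
    form_field("d", kind = "teleport", row = 2, col = 0),
    form_field("e", validator = "regex", row = 3, col = 0)))
  diags <- validate_schema(s)
  expect_true(any(grepl("duplicate grid position", diags)))
  expect_true(any(grepl("pulldown requires a value_list", diags)))
  expect_true(any(grepl("unknown kind", diags)))
  expect_true(any(grepl("regex validator without pattern", diags)))
  # a clean schema yields no diagnostics
  ok <- form_schema("f", list(
    form_field("a", row = 0, col = 0, required = TRUE),
    form_field("b", kind = "pulldown", row = 0, col = 1,
               validator = "value_list", values = c("x", "y"))),
    target_url = "http://db.example/submit")
  expect_identical(validate_schema(ok), character())
  # generated valid schemas stay clean
  set.seed(61)
  for (rep in 1:10) {
    n <- rand_int(1L, 6L)
    flds <- lapply(seq_len(n), function(i)
      form_field(paste0("f", i), kind = sample(c(
        "line_edit", "text_area", "checkbox"), 1L),
        row = i %/% 3L, col = i %% 3L))
    expect_identical(validate_schema(form_schema("g", flds)), character())
  }
})

test_that("prepopulation draws from static text, bibliography, and spans", {
  fx <- go_fixture()
  doc <- fx$doc
  schema <- form_schema("go_mf", list(
    form_field("term", row = 0, col = 0,
               prepopulate = "span_terms:GO:0004674"),
    form_field("anyterm", row = 0, col = 1, prepopulate = "span_terms:any"),
    form_field("ref", row = 1, col = 0, prepopulate = "biblio:accession"),
    form_field("note", row = 1, col = 1, prepopulate = "static:manual check"),
    form_field("blank", row = 2, col = 0)))
  # span covering the first sentence only
  sents <- doc_layer(doc, "sentence")
  spans <- data.frame(begin = sents$begin[1], end = sents$end[1])
  vals <- prepopulate(schema, doc, spans)
  expect_identical(
    vals$term,
    "protein serine/threonine kinase activity [GO:0004674]")
  # the nested "kinase activity" annotation sits inside the long form
  expect_true(grepl("kinase activity \\[GO:0016301\\]", vals$anyterm))
  expect_identical(vals$ref, "PM1")
  expect_identical(vals$note, "manual check")
  expect_identical(vals$blank, "")
  # only annotations fully inside a span are collected
  spans2 <- data.frame(begin = sents$begin[3], end = sents$end[3])
  expect_identical(prepopulate(schema, doc, spans2)$anyterm, "")
  # unknown bibliography field is a schema error
  bad <- form_schema("x", list(form_field("z", prepopulate = "biblio:nope")))
  expect_error(prepopulate(bad, doc, spans),
               class = "litmine_schema_error")
})

test_that("record validation enforces required, lists, categories, regex", {
  fx <- go_fixture()
  schema <- form_schema("go_mf", list(
    form_field("gene", row = 0, col = 0, required = TRUE),
    form_field("rel", kind = "pulldown", row = 0, col = 1,
               validator = "value_list", values = c("enables", "part_of")),
    form_field("term", row = 1, col = 0,
               validator = "category:GO:0016301"),
    form_field("date", row = 1, col = 1, validator = "regex",
               pattern = "\\d{4}-\\d{2}-\\d{2}")))
  rec <- curation_record(fx$doc, data.frame(begin = 0L, end = 10L),
                         field_values = list(
                           gene = "", rel = "maybe",
                           term = "something else [XX:1]",
                           date = "yesterday"))
  diags <- validate_record(schema, rec, fx$forest)
  expect_true(any(grepl("required field gene", diags)))
  expect_true(any(grepl("not in value list", diags)))
  expect_true(any(grepl("not found in category", diags)))
  expect_true(any(grepl("does not match pattern", diags)))

  good <- curation_record(fx$doc, data.frame(begin = 0L, end = 10L),
                          field_values = list(
                            gene = "zyg-1", rel = "enables",
                            term = "kinase activity [GO:0016301]",
                            date = "2026-01-15"))
  expect_identical(validate_record(schema, good, fx$forest), character())
  # bare name accepted through the expanded lexicon; bracketed child id too
  good$field_values$term <- "protein serine/threonine kinase activity"
  expect_identical(validate_record(schema, good, fx$forest), character())
  good$field_values$term <- "whatever [GO:0004674]"
  expect_identical(validate_record(schema, good, fx$forest), character())
})

test_that("export produces equivalent JSON and URI payloads (round-trip)", {
  fx <- go_fixture()
  doc <- fx$doc
  schema <- form_schema("noctua_go", list(
    form_field("term", row = 0, col = 0),
    form_field("note", row = 0, col = 1)),
    target_url = "http://noctua.example/form",
    transport = "parameterized_uri")
  sents <- doc_layer(doc, "sentence")
  # non-contiguous evidence spans (sentences 1 and 3)
  spans <- data.frame(begin = sents$begin[c(1, 3)],
                      end = sents$end[c(1, 3)])
  rec <- curation_record(
    doc, spans,
    field_values = list(term = "serine/threonine", note = "a&b =c?"),
    curator = "kv", timestamp = "2026-01-01T00:00:00Z", token = "abc123")
  uri <- export_record(schema, rec, doc, mode = "uri")
  json <- export_record(schema, rec, doc, mode = "json")
  expect_match(uri$body, "^http://noctua\\.example/form\\?")
  expect_match(uri$body, "token=abc123", fixed = TRUE)
  expect_match(uri$body, "serine%2Fthreonine", fixed = TRUE)
  dec_u <- decode_payload(uri$body, "uri")
  dec_j <- decode_payload(json$body, "json")
  expect_identical(dec_u, dec_j)
  expect_identical(dec_u$token, "abc123")
  expect_identical(dec_u$fields$term, "serine/threonine")
  expect_identical(dec_u$fields$note, "a&b =c?")
  # evidence text equals the SofA slice, byte for byte
  for (e in dec_u$evidence)
    expect_identical(e$text, substr(doc$sofa, e$begin + 1, e$end))
  # failing records refuse export with diagnostics
  bad_schema <- form_schema("noctua_go", list(
    form_field("term", row = 0, col = 0, required = TRUE)),
    target_url = "http://noctua.example/form")
  bad <- curation_record(doc, spans, field_values = list(term = ""))
  expect_error(export_record(bad_schema, bad, doc),
               class = "litmine_export_refused")
})

test_that("random records round-trip through both transports", {
  set.seed(62)
  fx <- go_fixture()
  doc <- fx$doc
  len <- nchar(doc$sofa)
  schema <- form_schema("f", list(
    form_field("a", row = 0, col = 0), form_field("b", row = 0, col = 1)),
    target_url = "http://db.example/x")
  rand_val <- function() {
    chars <- c(letters, LETTERS, 0:9, " ", "&", "=", "?", "/", "%", "+",
               "#", "[", "]", "é", "β")
    paste(sample(chars, rand_int(0L, 12L), replace = TRUE), collapse = "")
  }
  for (rep in 1:20) {
    b <- sort(sample.int(len - 2L, 2L))
    rec <- curation_record(
      doc, data.frame(begin = b[1] - 1L, end = b[2]),
      field_values = list(a = rand_val(), b = rand_val()),
      curator = rand_val(), timestamp = "2026-02-03T04:05:06Z",
      token = rand_val())
    for (mode in c("json", "uri")) {
      pl <- export_record(schema, rec, doc, mode = mode)
      dec <- decode_payload(pl$body, mode)
      expect_identical(dec$fields$a, rec$field_values$a)
      expect_identical(dec$fields$b, rec$field_values$b)
      expect_identical(dec$token, rec$token)
      expect_identical(dec$curator, rec$curator)
      expect_identical(vapply(dec$evidence, `[[`, 0L, "begin"),
                       rec$spans$begin)
      expect_identical(vapply(dec$evidence, `[[`, 0L, "end"),
                       rec$spans$end)
    }
  }
})

test_that("overlapping highlight selections are merged; bad spans rejected", {
  fx <- go_fixture()
  rec <- curation_record(fx$doc,
                         data.frame(begin = c(0L, 5L, 30L),
                                    end = c(10L, 12L, 40L)))
  expect_identical(rec$spans,
                   data.frame(begin = c(0L, 30L), end = c(12L, 40L)))
  expect_error(curation_record(fx$doc,
                               data.frame(begin = 5L, end = 5L)),
               class = "litmine_validation_error")
  expect_error(curation_record(fx$doc,
                               data.frame(begin = 0L, end = 99999L)),
               class = "litmine_validation_error")
})

test_that("schema JSON round-trips", {
  schema <- form_schema("go_mf", list(
    form_field("gene", row = 0, col = 0, required = TRUE,
               autocomplete = "category:GO:0016301"),
    form_field("rel", kind = "pulldown", row = 1, col = 0,
               validator = "value_list", values = c("enables", "part_of")),
    form_field("date", row = 2, col = 0, validator = "regex",
               pattern = "\\d{4}")),
    target_url = "http://db.example/x", transport = "parameterized_uri")
  p <- withr::local_tempfile(fileext = ".json")
  schema_save(schema, p)
  expect_equal(schema_load(p), schema)
})
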