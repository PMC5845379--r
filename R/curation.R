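#' @title Curation forms and span-linked annotation export
#'
#' @description Curators define custom forms (line edits, text areas,
#' pull-down menus, check boxes on a grid, each with optional
#' autocomplete source, validator and prepopulation rule), highlight
#' possibly non-contiguous evidence spans in a document, fill the form,
#' and export the record to an external database either as a JSON object
#' or as an RFC 3986 parameterized URI. An identity token received from
#' the external system is passed through verbatim so the annotation finds
#' its place there.
#'
#' @name curation
NULL

FIELD_KINDS <- c("line_edit", "text_area", "pulldown", "checkbox")

#' Define a curation form field
#'
#' @param field_id unique id within the form.
#' @param label display label.
#' @param kind one of `line_edit`, `text_area`, `pulldown`, `checkbox`.
#' @param row,col grid position (unique per form).
#' @param autocomplete `"none"`, `"value_list"`,
#'   `"category:<category_id>"` or `"external:<url template>"`.
#' @param validator `"none"`, `"value_list"`, `"category:<category_id>"`
#'   or `"regex"`.
#' @param prepopulate `"none"`, `"static:<text>"`, `"biblio:<field>"` or
#'   `"span_terms:<category_id or any>"`.
#' @param required must be non-empty and validator-passing before export.
#' @param values value list (for `value_list` sources and pulldowns).
#' @param pattern regular expression (for `validator = "regex"`; must
#'   match the entire value).
#' @return a `form_field` list.
#' @export
form_field <- function(field_id, label = field_id,
                       kind = "line_edit", row = 0L, col = 0L,
                       autocomplete = "none", validator = "none",
                       prepopulate = "none", required = FALSE,
                       values = character(), pattern = NULL) {
  structure(list(field_id = field_id, label = label, kind = kind,
                 row = as.integer(row), col = as.integer(col),
                 autocomplete = autocomplete, validator = validator,
                 prepopulate = prepopulate, required = isTRUE(required),
                 values = as.character(values), pattern = pattern),
            class = "form_field")
}

#' Define a curation form schema
#'
#' @param form_name name of the form.
#' @param fields list of [form_field()]s.
#' @param target_url URL the completed form is delivered to.
#' @param transport `"json_post"` or `"parameterized_uri"`.
#' @return a `form_schema` object.
#' @export
form_schema <- function(form_name, fields, target_url = "",
                        transport = c("json_post", "parameterized_uri")) {
  transport <- match.arg(transport)
  structure(list(form_name = form_name, fields = fields,
                 target_url = target_url, transport = transport),
            class = "form_schema")
}

#' Validate a form schema
#'
#' @param schema a [form_schema()].
#' @return character vector of diagnostics; empty iff the schema
#'   satisfies all invariants (unique field ids and grid positions, known
#'   kinds, pulldowns backed by a value list, regex validators carrying a
#'   pattern).
#' @export
validate_schema <- function(schema) {
  diags <- character()
  ids <- vapply(schema$fields, `[[`, "", "field_id")
  if (anyDuplicated(ids))
    diags <- c(diags, paste0("duplicate field_id: ",
                             paste(unique(ids[duplicated(ids)]),
                                   collapse = ", ")))
  pos <- vapply(schema$fields, function(f) paste(f$row, f$col), character(1))
  if (anyDuplicated(pos))
    diags <- c(diags, paste0("duplicate grid position for fields: ",
                             paste(ids[pos %in% pos[duplicated(pos)]],
                                   collapse = ", ")))
  for (f in schema$fields) {
    if (!(f$kind %in% FIELD_KINDS))
      diags <- c(diags, paste0("field ", f$field_id, ": unknown kind '",
                               f$kind, "'"))
    if (identical(f$kind, "pulldown") &&
        !(identical(f$autocomplete, "value_list") ||
          identical(f$validator, "value_list")) )
      diags <- c(diags, paste0("field ", f$field_id,
                               ": pulldown requires a value_list source"))
    if ((identical(f$autocomplete, "value_list") ||
         identical(f$validator, "value_list")) && !length(f$values))
      diags <- c(diags, paste0("field ", f$field_id,
                               ": value_list source without values"))
    if (identical(f$validator, "regex") && is.null(f$pattern))
      diags <- c(diags, paste0("field ", f$field_id,
                               ": regex validator without pattern"))
    if (!grepl("^(none|static:|biblio:|span_terms:)", f$prepopulate))
      diags <- c(diags, paste0("field ", f$field_id,
                               ": unknown prepopulate rule '",
                               f$prepopulate, "'"))
  }
  diags
}

merge_spans <- function(spans) {
  if (!nrow(spans)) return(spans)
  spans <- spans[order(spans$begin, spans$end), , drop = FALSE]
  out_b <- spans$begin[1L]; out_e <- spans$end[1L]
  if (nrow(spans) > 1L) for (i in 2L:nrow(spans)) {
    if (spans$begin[i] <= out_e[length(out_e)]) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], spans$end[i])
    } else {
      out_b <- c(out_b, spans$begin[i]); out_e <- c(out_e, spans$end[i])
    }
  }
  data.frame(begin = out_b, end = out_e)
}

#' Create a curation record
#'
#' @param doc the `litdoc` being curated.
#' @param spans data frame with `begin`, `end` (0-based half-open offsets
#'   into the SofA); may be non-contiguous — curators collect evidence
#'   statements throughout a paper. Overlapping selections are merged.
#' @param field_values named list/character vector of field values.
#' @param curator curator name.
#' @param timestamp character timestamp (defaults to current UTC time).
#' @param token opaque identity token from the external system (may be
#'   empty); passed through verbatim on export.
#' @param record_id record identifier.
#' @return a `curation_record`.
#' @export
curation_record <- function(doc, spans, field_values = list(),
                            curator = "", timestamp = NULL, token = "",
                            record_id = "r1") {
  stopifnot(inherits(doc, "litdoc"))
  spans <- data.frame(begin = as.integer(spans$begin),
                      end = as.integer(spans$end))
  len <- nchr(doc$sofa)
  if (nrow(spans) &&
      any(spans$begin < 0L | spans$begin >= spans$end | spans$end > len))
    stop_litmine("evidence span out of range for document ", doc$doc_id,
                 class = "litmine_validation_error")
  spans <- merge_spans(spans)
  if (is.null(timestamp))
    timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  fv <- as.list(field_values)
  structure(list(record_id = record_id, doc_id = doc$doc_id,
                 spans = spans, field_values = fv, curator = curator,
                 timestamp = timestamp, token = token),
            class = "curation_record")
}

biblio_field_text <- function(bib, name) {
  if (!name %in% names(bib))
    stop_litmine("unknown bibliography field '", name, "'",
                 class = "litmine_schema_error")
  v <- bib[[name]]
  if (name == "authors") return(paste(v, collapse = "; "))
  if (name == "subjects") return(paste(v, collapse = "; "))
  if (length(v) == 0L || is.na(v)) return("")
  as.character(v)
}

#' Prepopulate form fields from a document and highlighted spans
#'
#' `static:<text>` yields the literal text; `biblio:<field>` the rendered
#' bibliography field; `span_terms:<category_id or any>` the
#' semicolon-joined `"surface form [term id]"` entries of every lexical
#' annotation of that category (or any category) lying fully inside one
#' of the highlighted spans, deduplicated, in document order.
#'
#' @param schema a [form_schema()].
#' @param doc a `litdoc` (stage >= 2 for `span_terms`).
#' @param spans evidence spans (data frame `begin`, `end`).
#' @return named list of field values (unpopulated fields are `""`).
#' @export
prepopulate <- function(schema, doc, spans = data.frame(begin = integer(),
                                                        end = integer())) {
  lex <- doc_layer(doc, "lexical")
  out <- list()
  for (f in schema$fields) {
    val <- ""
    if (grepl("^static:", f$prepopulate)) {
      val <- sub("^static:", "", f$prepopulate)
    } else if (grepl("^biblio:", f$prepopulate)) {
      val <- biblio_field_text(doc$bibliography,
                               sub("^biblio:", "", f$prepopulate))
    } else if (grepl("^span_terms:", f$prepopulate)) {
      want <- sub("^span_terms:", "", f$prepopulate)
      if (nrow(lex) && nrow(spans)) {
        inside <- vapply(seq_len(nrow(lex)), function(i)
          any(spans$begin <= lex$begin[i] & spans$end >= lex$end[i]),
          logical(1))
        sel <- lex[inside, , drop = FALSE]
        if (want != "any") {
          cats <- vapply(sel$attributes, function(a)
            unname(a[["category_id"]]), character(1))
          sel <- sel[cats == want, , drop = FALSE]
        }
        if (nrow(sel)) {
          entries <- vapply(seq_len(nrow(sel)), function(i) {
            a <- sel$attributes[[i]]
            tid <- if ("term_id" %in% names(a)) a[["term_id"]]
                   else a[["category_id"]]
            sprintf("%s [%s]", a[["matched_form"]], tid)
          }, character(1))
          val <- paste(unique(entries), collapse = "; ")
        }
      }
    }
    out[[f$field_id]] <- val
  }
  out
}

#' Validate a filled record against its schema
#'
#' Checks that required fields are present and non-empty, value-list
#' membership, category validators (the value's bracketed id — or its
#' bare name — must exist in the category's expanded lexicon/term set),
#' and regex validators (entire value must match).
#'
#' @param schema a [form_schema()].
#' @param record a [curation_record()].
#' @param forest the `category_forest` backing category validators.
#' @return character vector of diagnostics; empty iff exportable.
#' @export
validate_record <- function(schema, record, forest = NULL) {
  diags <- character()
  fv <- record$field_values
  for (f in schema$fields) {
    val <- fv[[f$field_id]] %||% ""
    if (f$required && !nzchar(trimws2(val))) {
      diags <- c(diags, paste0("required field ", f$field_id, " is empty"))
      next
    }
    if (!nzchar(val)) next
    if (identical(f$validator, "value_list") && !(val %in% f$values))
      diags <- c(diags, paste0("field ", f$field_id, ": value '", val,
                               "' not in value list"))
    if (grepl("^category:", f$validator)) {
      cat_id <- sub("^category:", "", f$validator)
      if (is.null(forest) || !cat_id %in% names(forest$nodes)) {
        diags <- c(diags, paste0("field ", f$field_id,
                                 ": validator category '", cat_id,
                                 "' not available"))
      } else {
        lex <- expand_with_children(forest, cat_id, children = TRUE)
        m <- regmatches(val, regexec("^(.*?)\\s*\\[([^]]+)\\]$", val))[[1]]
        ok <- if (length(m) == 3L)
          m[3] %in% c(lex$source_id, lex$origin, cat_id)
        else val %in% lex$surface_form
        if (!ok)
          diags <- c(diags, paste0("field ", f$field_id, ": value '", val,
                                   "' not found in category ", cat_id))
      }
    }
    if (identical(f$validator, "regex") && !is.null(f$pattern) &&
        !grepl(paste0("^(?:", f$pattern, ")$"), val, perl = TRUE))
      diags <- c(diags, paste0("field ", f$field_id, ": value '", val,
                               "' does not match pattern"))
  }
  diags
}

payload_content <- function(schema, record, doc) {
  ev <- lapply(seq_len(nrow(record$spans)), function(i)
    list(begin = record$spans$begin[i], end = record$spans$end[i],
         text = substr(doc$sofa, record$spans$begin[i] + 1L,
                       record$spans$end[i])))
  fields <- record$field_values
  if (!length(fields)) fields <- structure(list(), names = character())
  list(form_name = schema$form_name,
       accession = doc$bibliography$accession,
       evidence = ev, fields = fields, curator = record$curator,
       timestamp = record$timestamp, token = record$token)
}

#' Export a curation record
#'
#' Refuses export (with the diagnostics) unless [validate_record()] is
#' clean. Evidence text slices are taken verbatim from the SofA; the
#' identity token is copied through unchanged.
#'
#' @param schema a [form_schema()].
#' @param record a [curation_record()].
#' @param doc the `litdoc` the record refers to.
#' @param forest optional `category_forest` for category validators.
#' @param mode `"json"` or `"uri"`; defaults to the schema transport.
#' @return an `export_payload`: `list(mode, target_url, content, body)`
#'   where `body` is the JSON text (json mode) or the full encoded URI.
#' @export
export_record <- function(schema, record, doc, forest = NULL, mode = NULL) {
  diags <- c(validate_schema(schema), validate_record(schema, record, forest))
  if (length(diags))
    stop_litmine("export refused:\n  - ", paste(diags, collapse = "\n  - "),
                 class = "litmine_export_refused")
  if (record$doc_id != doc$doc_id)
    stop_litmine("record refers to document ", record$doc_id, ", not ",
                 doc$doc_id, class = "litmine_validation_error")
  if (is.null(mode))
    mode <- if (identical(schema$transport, "parameterized_uri")) "uri"
            else "json"
  content <- payload_content(schema, record, doc)
  if (mode == "json") {
    body <- as.character(jsonlite::toJSON(content, auto_unbox = TRUE,
                                          digits = NA))
  } else {
    kv <- c(form_name = content$form_name, accession = content$accession,
            curator = content$curator, timestamp = content$timestamp,
            token = content$token)
    for (i in seq_along(content$evidence)) {
      e <- content$evidence[[i]]
      kv[paste0("evidence.", i - 1L, ".begin")] <- as.character(e$begin)
      kv[paste0("evidence.", i - 1L, ".end")] <- as.character(e$end)
      kv[paste0("evidence.", i - 1L, ".text")] <- e$text
    }
    for (nm in names(content$fields))
      kv[paste0("field.", nm)] <- as.character(content$fields[[nm]])
    body <- paste0(schema$target_url, "?",
                   paste(paste0(percent_encode(names(kv)), "=",
                                percent_encode(unname(kv))),
                         collapse = "&"))
  }
  structure(list(mode = mode, target_url = schema$target_url,
                 content = content, body = body),
            class = "export_payload")
}

#' Decode an exported payload back to its content
#'
#' Inverse of [export_record()] for both modes; used to verify the
#' round-trip law (decode(encode(record)) recovers all values exactly).
#'
#' @param body JSON text or parameterized URI string.
#' @param mode `"json"` or `"uri"`.
#' @return the content list (form_name, accession, evidence, fields,
#'   curator, timestamp, token).
#' @export
decode_payload <- function(body, mode = c("json", "uri")) {
  mode <- match.arg(mode)
  if (mode == "json") {
    l <- jsonlite::fromJSON(body, simplifyVector = FALSE)
    l$evidence <- lapply(l$evidence, function(e)
      list(begin = as.integer(e$begin), end = as.integer(e$end),
           text = e$text))
    if (!length(l$fields)) l$fields <- structure(list(), names = character())
    return(l)
  }
  q <- sub("^[^?]*\\?", "", body)
  parts <- strsplit(q, "&", fixed = TRUE)[[1]]
  keys <- percent_decode(sub("=.*$", "", parts))
  vals <- percent_decode(sub("^[^=]*=", "", parts))
  names(vals) <- keys
  ev_idx <- sort(unique(as.integer(
    sub("^evidence\\.(\\d+)\\..*$", "\\1",
        keys[grepl("^evidence\\.", keys)]))))
  evidence <- lapply(ev_idx, function(i)
    list(begin = as.integer(vals[[paste0("evidence.", i, ".begin")]]),
         end = as.integer(vals[[paste0("evidence.", i, ".end")]]),
         text = vals[[paste0("evidence.", i, ".text")]]))
  fkeys <- keys[grepl("^field\\.", keys)]
  fields <- structure(lapply(fkeys, function(k) unname(vals[[k]])),
                      names = sub("^field\\.", "", fkeys))
  if (!length(fields)) fields <- structure(list(), names = character())
  list(form_name = unname(vals[["form_name"]]),
       accession = unname(vals[["accession"]]),
       evidence = evidence, fields = fields,
       curator = unname(vals[["curator"]]),
       timestamp = unname(vals[["timestamp"]]),
       token = unname(vals[["token"]]))
}

#' Save / load a form schema as JSON
#'
#' @param schema a [form_schema()].
#' @param path file path.
#' @return `schema_save`: path invisibly; `schema_load`: the schema.
#' @export
schema_save <- function(schema, path) {
  fields <- lapply(schema$fields, function(f) {
    l <- f[c("field_id", "label", "kind", "row", "col", "autocomplete",
             "validator", "prepopulate", "required")]
    l$values <- as.list(f$values)
    if (!is.null(f$pattern)) l$pattern <- f$pattern
    l
  })
  json_write_canonical(list(form_name = schema$form_name, fields = fields,
                            target_url = schema$target_url,
                            transport = schema$transport), path)
}

#' @rdname schema_save
#' @export
schema_load <- function(path) {
  l <- json_read(path)
  fields <- lapply(l$fields, function(f)
    form_field(field_id = f$field_id, label = f$label %||% f$field_id,
               kind = f$kind %||% "line_edit", row = f$row %||% 0L,
               col = f$col %||% 0L,
               autocomplete = f$autocomplete %||% "none",
               validator = f$validator %||% "none",
               prepopulate = f$prepopulate %||% "none",
               required = isTRUE(f$required),
               values = as_chr(f$values %||% list()),
               pattern = f$pattern))
  form_schema(l$form_name, fields, l$target_url %||% "",
              l$transport %||% "json_post")
}
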