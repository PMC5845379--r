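`%||%` <- function(x, y) if (is.null(x)) y else x

nchr <- function(x) nchar(x, type = "chars")

trimws2 <- function(x) gsub("^\\s+|\\s+$", "", x, perl = TRUE)

# collapse runs of whitespace to a single space and trim
squish <- function(x) trimws2(gsub("\\s+", " ", x, perl = TRUE))

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stop_litmine <- function(..., class = "litmine_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# RFC 3986 percent-encoding over the unreserved set; exact inverse of
# percent_decode for any UTF-8 string.
percent_encode <- function(x) {
  vapply(x, function(s) {
    raw <- charToRaw(enc2utf8(s))
    b <- as.integer(raw)
    keep <- (b >= 0x30 & b <= 0x39) | (b >= 0x41 & b <= 0x5A) |
      (b >= 0x61 & b <= 0x7A) | b %in% c(0x2DL, 0x2EL, 0x5FL, 0x7EL)
    out <- character(length(raw))
    out[keep] <- vapply(which(keep), function(i) rawToChar(raw[i]), "")
    out[!keep] <- sprintf("%%%02X", b[!keep])
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

percent_decode <- function(x) {
  vapply(x, function(s) {
    out <- raw(0)
    i <- 1L
    raw_s <- charToRaw(s)
    n <- length(raw_s)
    while (i <= n) {
      b <- raw_s[i]
      if (b == charToRaw("%") && i + 2L <= n) {
        out <- c(out, as.raw(strtoi(rawToChar(raw_s[(i + 1L):(i + 2L)]), 16L)))
        i <- i + 3L
      } else {
        out <- c(out, b)
        i <- i + 1L
      }
    }
    s2 <- rawToChar(out)
    Encoding(s2) <- "UTF-8"
    s2
  }, character(1), USE.NAMES = FALSE)
}

json_write_canonical <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null",
                          null = "null", pretty = FALSE)
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

json_read <- function(path) jsonlite::read_json(path, simplifyVector = FALSE)

as_chr <- function(x) vapply(x, function(e) as.character(e), character(1))
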