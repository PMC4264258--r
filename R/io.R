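# JSON Lines I/O for documents, annotations and gold standoff labels.
# One object per line; all character offsets 0-based, half-open.

#' Read documents from JSON Lines
#'
#' One object per line with fields `id`, `doc_type` (GP|SP|RD|DL) and
#' `text`; an optional `reference_year` enables year-based temporal
#' patterns.
#'
#' @param path Path to the JSONL file.
#' @return Data frame with columns `id`, `doc_type`, `text`,
#'   `reference_year`.
#' @export
read_documents <- function(path) {
  if (!file.exists(path)) stop("documents file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("documents file is empty: ", path)
    return(data.frame(id = character(), doc_type = character(),
                      text = character(), reference_year = integer(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_along(lines), function(i) {
    o <- jsonlite::fromJSON(lines[[i]])
    if (is.null(o$id) || is.null(o$doc_type) || is.null(o$text)) {
      stop("document at line ", i, " lacks id/doc_type/text")
    }
    if (!o$doc_type %in% DOC_TYPES) {
      stop("unknown doc_type '", o$doc_type, "' (doc ", o$id, ")")
    }
    data.frame(id = as.character(o$id), doc_type = o$doc_type,
               text = o$text,
               reference_year = if (is.null(o$reference_year)) NA_integer_
                                else as.integer(o$reference_year),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write documents to JSON Lines
#' @param docs Data frame with `id`, `doc_type`, `text`.
#' @param path Output path.
#' @export
write_documents <- function(docs, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(docs))) {
    o <- list(id = docs$id[[i]], doc_type = docs$doc_type[[i]],
              text = docs$text[[i]])
    if ("reference_year" %in% names(docs) &&
        !is.na(docs$reference_year[[i]])) {
      o$reference_year <- docs$reference_year[[i]]
    }
    writeLines(jsonlite::toJSON(o, auto_unbox = TRUE), con,
               useBytes = TRUE)
  }
  invisible(path)
}

annotation_columns <- function() {
  c("doc_id", "doc_type", "sentence_index", "char_start", "char_end",
    "term", "negation", "temporality", "experiencer")
}

#' Write annotations (or gold labels) to JSON Lines
#'
#' One object per mention; `evidence` (when present) is serialized as
#' an array of `{property, phrase_or_rule, char_start, char_end}`.
#'
#' @param ann Annotation data frame.
#' @param path Output path.
#' @export
write_annotations <- function(ann, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  has_ev <- "evidence" %in% names(ann)
  for (i in seq_len(nrow(ann))) {
    o <- as.list(ann[i, intersect(annotation_columns(), names(ann)),
                     drop = FALSE])
    o <- lapply(o, function(x) x[[1]])
    if (has_ev) {
      ev <- ann$evidence[[i]]
      o$evidence <- if (is.null(ev) || nrow(ev) == 0) list() else ev
    }
    writeLines(jsonlite::toJSON(o, auto_unbox = TRUE, dataframe = "rows",
                                na = "null"), con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read annotations from JSON Lines
#' @param path Path to the JSONL file.
#' @return Annotation data frame with an `evidence` list-column.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotations file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    out <- data.frame(doc_id = character(), doc_type = character(),
                      sentence_index = integer(), char_start = integer(),
                      char_end = integer(), term = character(),
                      negation = character(), temporality = character(),
                      experiencer = character(), stringsAsFactors = FALSE)
    out$evidence <- list()
    return(out)
  }
  rows <- lapply(lines, function(l) {
    o <- jsonlite::fromJSON(l, simplifyDataFrame = TRUE)
    ev <- o$evidence
    o$evidence <- NULL
    r <- as.data.frame(o[!vapply(o, is.null, logical(1))],
                       stringsAsFactors = FALSE)
    r$evidence <- list(if (is.data.frame(ev)) ev else empty_evidence())
    r
  })
  out <- do.call(rbind, rows)
  out$sentence_index <- as.integer(out$sentence_index)
  out$char_start <- as.integer(out$char_start)
  out$char_end <- as.integer(out$char_end)
  out
}
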