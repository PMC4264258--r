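# Text preparation: sentence splitting, offset-preserving tokenization,
# and concept marking by case-insensitive exact term matching.
#
# All offsets are 0-based, half-open, into the sentence text.

# Punctuation characters that become standalone tokens.  A hyphen
# directly attached to a preceding word stays attached (the GP minus
# convention "koorts-" must survive tokenization as one token).
PUNCT_CHARS <- c(",", ";", ":", ".", "-", "<", ">")

TOKEN_PATTERN <- "[^\\s,;:.<>-]+(?:-[^\\s,;:.<>-]+)*-?|[,;:.<>-]"

#' Tokenize sentence text with exact character offsets
#'
#' Splits on whitespace; the punctuation characters `, ; : . - < >`
#' become standalone tokens, except a hyphen attached to the end of a
#' word (`"koorts-"`) or joining two words (`"koorts-achtig"`), which
#' stays inside the word token.
#'
#' @param text Sentence text.
#' @return Data frame with columns `surface`, `start`, `end` (0-based,
#'   half-open); zero rows for empty input.
#' @export
tokenize <- function(text) {
  if (!nzchar(text)) {
    return(data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  m <- gregexpr(TOKEN_PATTERN, text, perl = TRUE)[[1]]
  if (m[[1]] == -1) {
    return(data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(surface = substring(text, start + 1L, start + len),
             start = start, end = start + as.integer(len),
             stringsAsFactors = FALSE)
}

is_punct_token <- function(surface) surface %in% PUNCT_CHARS

#' Default Dutch clinical abbreviation stop-list for sentence splitting
#' @return Character vector of abbreviations (without trailing period).
#' @export
dutch_abbreviations <- function() {
  c("dhr", "mevr", "mw", "dr", "drs", "prof", "st", "pat", "bijv", "evt",
    "ca", "vlgs", "fam", "anamn", "o.a", "i.v.m", "t.g.v", "z.n", "m.i",
    "b.v", "wv", "tel", "afd", "lab", "med", "no", "nr")
}

#' Construct a sentence object with tokens
#'
#' @param text Sentence text (trimmed).
#' @param doc_id Document identifier.
#' @param index_in_doc 0-based sentence index within the document.
#' @param start 0-based character offset of the sentence in the document.
#' @return List of class `clinical_sentence`.
#' @export
sentence <- function(text, doc_id = "", index_in_doc = 0L, start = 0L) {
  structure(list(text = text, tokens = tokenize(text), doc_id = doc_id,
                 index_in_doc = as.integer(index_in_doc),
                 start = as.integer(start)),
            class = "clinical_sentence")
}

#' @export
print.clinical_sentence <- function(x, ...) {
  cat("<sentence ", x$doc_id, "#", x$index_in_doc, "> ", x$text, "\n",
      sep = "")
  invisible(x)
}

#' Split a document into sentences
#'
#' Rule-based: a run of `. ! ?` ends a sentence when followed by
#' whitespace and an uppercase letter or digit, unless the word before a
#' period is on the abbreviation stop-list or is a single letter
#' (initials).  Context never crosses a sentence boundary downstream, so
#' over-splitting is the more harmful failure mode and the rules are
#' conservative.  Pre-split input can bypass this entirely: pass one
#' sentence per call to [sentence()].
#'
#' @param document_text Full document text.
#' @param doc_id Document identifier carried into each sentence.
#' @param abbreviations Stop-list of abbreviations (lowercase, no
#'   trailing period).
#' @return List of `clinical_sentence` objects (empty for blank input).
#' @export
split_sentences <- function(document_text, doc_id = "",
                            abbreviations = dutch_abbreviations()) {
  if (!nzchar(trimws(document_text))) return(list())
  chars <- strsplit(document_text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  breaks <- integer()  # index of last char of each sentence (1-based)
  i <- 1L
  while (i <= n) {
    ch <- chars[[i]]
    if (ch %in% c(".", "!", "?")) {
      # consume the full punctuation run
      j <- i
      while (j < n && chars[[j + 1L]] %in% c(".", "!", "?")) j <- j + 1L
      # look ahead: whitespace then uppercase/digit required
      k <- j + 1L
      while (k <= n && grepl("[ \t\r\n]", chars[[k]])) k <- k + 1L
      ok <- k > j + 1L && (k > n || grepl("[[:upper:][:digit:]]", chars[[k]]))
      if (ok && ch == ".") {
        # abbreviation / initial guard on the word preceding the period
        w_end <- i - 1L
        w_start <- w_end
        while (w_start >= 1L && !grepl("[ \t\r\n]", chars[[w_start]])) {
          w_start <- w_start - 1L
        }
        word <- tolower(paste(chars[seq.int(w_start + 1L, max(w_start + 1L, w_end))],
                              collapse = ""))
        word <- sub("\\.+$", "", word)
        if (w_end >= w_start + 1L &&
            (word %in% abbreviations || grepl("^[a-z]$", word))) {
          ok <- FALSE
        }
      }
      if (ok) breaks <- c(breaks, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  bounds <- c(0L, breaks, n)
  out <- list()
  idx <- 0L
  for (b in seq_len(length(bounds) - 1L)) {
    lo <- bounds[[b]] + 1L
    hi <- bounds[[b + 1L]]
    seg <- substring(document_text, lo, hi)
    # trim but keep the offset of the first retained character
    lead <- nchar(seg) - nchar(sub("^[ \t\r\n]+", "", seg))
    seg_trim <- trimws(seg)
    if (!nzchar(seg_trim)) next
    out[[length(out) + 1L]] <- sentence(seg_trim, doc_id = doc_id,
                                        index_in_doc = idx,
                                        start = lo - 1L + lead)
    idx <- idx + 1L
  }
  out
}

#' Read a term list
#'
#' One term per line, UTF-8; `#` starts a comment; blank lines ignored;
#' internal whitespace normalized to single spaces.
#'
#' @param path Path to the term-list file.
#' @return Character vector of terms.
#' @export
read_terms <- function(path) {
  if (!file.exists(path)) stop("term list not found: ", path)
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- gsub("[ \t]+", " ", trimws(x))
  unique(x[nzchar(x)])
}

#' Mark concept mentions in a sentence by exact term matching
#'
#' Case-insensitive exact string matching, aligned to token boundaries
#' (so "oma" never matches inside "stoma"); a mention may additionally
#' end just before a trailing hyphen of its final token, which is what
#' makes the GP minus form "koorts-" yield the mention "koorts".
#' Overlapping candidates are resolved longest-first, then leftmost.
#'
#' @param sent A `clinical_sentence`.
#' @param terms Character vector of terms (the role of a UMLS-derived
#'   Dutch term list).
#' @return Data frame of mentions: `term`, `char_start`, `char_end`,
#'   `token_start`, `token_end`, `concept_id`.
#' @export
match_concepts <- function(sent, terms) {
  stopifnot(inherits(sent, "clinical_sentence"))
  empty <- data.frame(term = character(), char_start = integer(),
                      char_end = integer(), token_start = integer(),
                      token_end = integer(), concept_id = character(),
                      stringsAsFactors = FALSE)
  if (length(terms) == 0 || nrow(sent$tokens) == 0) return(empty)
  toks <- sent$tokens
  cand <- list()
  for (term in terms) {
    pat <- gsub(" ", "\\\\s+", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", term))
    m <- gregexpr(pat, sent$text, ignore.case = TRUE, perl = TRUE)[[1]]
    if (m[[1]] == -1) next
    for (k in seq_along(m)) {
      cs <- as.integer(m[[k]]) - 1L
      ce <- cs + attr(m, "match.length")[[k]]
      ts <- which(toks$start == cs)
      if (length(ts) != 1) next
      te <- which(toks$end == ce)
      if (length(te) != 1) {
        # allow the match to stop just before a trailing hyphen
        te <- which(toks$end == ce + 1L &
                      substring(toks$surface, nchar(toks$surface)) == "-")
        if (length(te) != 1) next
      }
      if (te < ts) next
      cand[[length(cand) + 1L]] <- data.frame(
        term = term, char_start = cs, char_end = ce,
        token_start = ts - 1L, token_end = te,  # 0-based half-open
        concept_id = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)
  # longest match, then leftmost: greedy selection without overlap
  ord <- order(-(cand$char_end - cand$char_start), cand$char_start)
  cand <- cand[ord, ]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ov <- keep & cand$char_start < cand$char_end[[i]] &
      cand$char_end > cand$char_start[[i]]
    keep[[i]] <- !any(ov)
  }
  res <- cand[keep, ]
  res <- res[order(res$char_start), ]
  rownames(res) <- NULL
  res
}
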