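# Core context engine: find trigger occurrences, resolve their scopes
# under a document-type profile, and assign contextual property values
# to marked concepts.
#
# Default property values: NotNegated / Recent / Patient.  A value is
# changed only when the concept falls inside the resolved scope of a
# trigger, or a document-specific rule fires.

#' Document-type scope profile
#'
#' Per-document-type parameters of the scope model:
#' * GP entries: default scope of 6 words, comma and semicolon act as
#'   scope terminators, the minus-sign negation rule is active;
#' * specialist letters: 10 words, colon and semicolon terminate;
#' * radiology reports and discharge letters: scope runs to the sentence
#'   boundary, no punctuation terminators.
#'
#' Scope lengths are counted in words, i.e. non-punctuation tokens.
#'
#' @param doc_type One of `DOC_TYPES`.
#' @param default_scope_tokens Override the default scope cap (`Inf`
#'   means sentence end).
#' @param punctuation_terminators Override the punctuation terminator
#'   set.
#' @param gp_minus_rule_active,combined_rules_active Override rule gates.
#' @return Object of class `document_profile`.
#' @export
document_profile <- function(doc_type,
                             default_scope_tokens = NULL,
                             punctuation_terminators = NULL,
                             gp_minus_rule_active = NULL,
                             combined_rules_active = TRUE) {
  doc_type <- match.arg(doc_type, DOC_TYPES)
  base <- switch(doc_type,
    GP = list(scope = 6, punct = c(",", ";"), minus = TRUE),
    SP = list(scope = 10, punct = c(":", ";"), minus = FALSE),
    RD = list(scope = Inf, punct = character(), minus = FALSE),
    DL = list(scope = Inf, punct = character(), minus = FALSE))
  structure(list(
    doc_type = doc_type,
    default_scope_tokens = if (is.null(default_scope_tokens)) base$scope
                           else default_scope_tokens,
    punctuation_terminators = if (is.null(punctuation_terminators))
                                base$punct else punctuation_terminators,
    gp_minus_rule_active = if (is.null(gp_minus_rule_active)) base$minus
                           else gp_minus_rule_active,
    combined_rules_active = combined_rules_active),
    class = "document_profile")
}

#' @export
print.document_profile <- function(x, ...) {
  cat("<document_profile ", x$doc_type, "> scope=",
      if (is.infinite(x$default_scope_tokens)) "sentence-end"
      else x$default_scope_tokens,
      " terminators={", paste(x$punctuation_terminators, collapse = " "),
      "} minus-rule=", x$gp_minus_rule_active, "\n", sep = "")
  invisible(x)
}

empty_occurrences <- function() {
  data.frame(phrase = character(), property = character(),
             role = character(), token_start = integer(),
             token_end = integer(), char_start = integer(),
             char_end = integer(), max_scope_tokens = integer(),
             stringsAsFactors = FALSE)
}

# Phrase tokenizations are cached: lexicons are scanned against every
# sentence, and re-tokenizing each phrase per sentence dominates runtime
# on corpora of thousands of sentences.
.phrase_cache <- new.env(parent = emptyenv())

phrase_tokens <- function(phrase) {
  hit <- .phrase_cache[[phrase]]
  if (!is.null(hit)) return(hit)
  val <- tolower(tokenize(phrase)$surface)
  assign(phrase, val, envir = .phrase_cache)
  val
}

# Scan sentence tokens for occurrences of one tokenized phrase.
# Returns 0-based half-open token intervals.
scan_phrase <- function(toks_lower, phrase_tokens) {
  np <- length(phrase_tokens)
  nt <- length(toks_lower)
  if (np == 0 || nt < np) return(integer())
  hits <- integer()
  for (i in seq_len(nt - np + 1L)) {
    if (all(toks_lower[i:(i + np - 1L)] == phrase_tokens)) {
      hits <- c(hits, i - 1L)
    }
  }
  hits
}

#' Find trigger occurrences in a sentence
#'
#' Case-insensitive, token-boundary, longest-match scan of the lexicon
#' entries applicable to the document type.  Within one (property, role)
#' no occurrence strictly contained in another is kept, and a pseudo
#' occurrence masks every shorter non-pseudo occurrence fully inside its
#' span -- a pseudo trigger's whole purpose is to neutralize a lookalike
#' (e.g. "niet minder" absorbing "niet").
#'
#' @param sent A `clinical_sentence`.
#' @param lex A `trigger_lexicon`.
#' @param doc_type One of `DOC_TYPES`.
#' @return Data frame of occurrences ordered left to right: `phrase`,
#'   `property`, `role`, `token_start`, `token_end`, `char_start`,
#'   `char_end`, `max_scope_tokens`.
#' @export
find_triggers <- function(sent, lex, doc_type) {
  stopifnot(inherits(sent, "clinical_sentence"),
            inherits(lex, "trigger_lexicon"))
  doc_type <- match.arg(doc_type, DOC_TYPES)
  e <- lex$entries[doc_types_match(lex$entries$doc_types, doc_type), ,
                   drop = FALSE]
  toks <- sent$tokens
  if (nrow(e) == 0 || nrow(toks) == 0) return(empty_occurrences())
  toks_lower <- tolower(toks$surface)
  occ <- list()
  for (i in seq_len(nrow(e))) {
    pt <- phrase_tokens(e$phrase[[i]])
    for (ts in scan_phrase(toks_lower, pt)) {
      te <- ts + length(pt)
      occ[[length(occ) + 1L]] <- data.frame(
        phrase = e$phrase[[i]], property = e$property[[i]],
        role = e$role[[i]], token_start = ts, token_end = te,
        char_start = toks$start[[ts + 1L]], char_end = toks$end[[te]],
        max_scope_tokens = e$max_scope_tokens[[i]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(occ) == 0) return(empty_occurrences())
  occ <- do.call(rbind, occ)
  len <- occ$token_end - occ$token_start
  # longest match within (property, role)
  keep <- rep(TRUE, nrow(occ))
  for (i in seq_len(nrow(occ))) {
    contained <- occ$property == occ$property[[i]] &
      occ$role == occ$role[[i]] &
      occ$token_start <= occ$token_start[[i]] &
      occ$token_end >= occ$token_end[[i]] & len > len[[i]]
    if (any(contained)) keep[[i]] <- FALSE
  }
  occ <- occ[keep, , drop = FALSE]
  # pseudo masking
  ps <- occ[occ$role == "pseudo", , drop = FALSE]
  if (nrow(ps) > 0) {
    masked <- vapply(seq_len(nrow(occ)), function(i) {
      occ$role[[i]] != "pseudo" &&
        any(ps$token_start <= occ$token_start[[i]] &
              ps$token_end >= occ$token_end[[i]])
    }, logical(1))
    occ <- occ[!masked, , drop = FALSE]
  }
  occ <- occ[order(occ$token_start, occ$token_end), , drop = FALSE]
  rownames(occ) <- NULL
  occ
}

#' Resolve the scope of a pre- or post-trigger occurrence
#'
#' A pre-trigger's scope runs rightwards from the trigger to the end of
#' the sentence; a post-trigger's leftwards to the beginning.  The
#' profile caps the scope at `default_scope_tokens` words (punctuation
#' tokens do not consume scope), an entry-level `max_scope_tokens`
#' overrides that cap, and the scope is truncated before the first
#' termination trigger of the same property or profile punctuation
#' terminator.
#'
#' @param occ One occurrence (single row of [find_triggers()] output).
#' @param sent The sentence.
#' @param profile A `document_profile`.
#' @param terminators Occurrences with role `"termination"` (same data
#'   frame shape); only same-property ones terminate.
#' @return Integer vector `c(start, end)`, a 0-based half-open token
#'   interval (possibly empty, `start == end`).
#' @export
resolve_scope <- function(occ, sent, profile,
                          terminators = empty_occurrences()) {
  role <- occ$role[[1]]
  if (!role %in% c("pre", "post")) stop("no scope for role ", role)
  toks <- sent$tokens
  n <- nrow(toks)
  cap <- occ$max_scope_tokens[[1]]
  if (is.na(cap)) cap <- profile$default_scope_tokens
  # tokens that stop a scope: any token covered by a same-property
  # termination occurrence, or a punctuation terminator of the profile
  stop_tok <- rep(FALSE, n)
  if (nrow(terminators) > 0) {
    tm <- terminators[terminators$role == "termination" &
                        terminators$property == occ$property[[1]], ,
                      drop = FALSE]
    for (i in seq_len(nrow(tm))) {
      stop_tok[seq.int(tm$token_start[[i]] + 1L, tm$token_end[[i]])] <- TRUE
    }
  }
  stop_tok <- stop_tok | toks$surface %in% profile$punctuation_terminators
  if (role == "pre") {
    lo <- occ$token_end[[1]]  # 0-based index of first candidate token
    i <- lo
    words <- 0
    while (i < n) {
      if (stop_tok[[i + 1L]]) break
      if (!is_punct_token(toks$surface[[i + 1L]])) {
        words <- words + 1
      }
      i <- i + 1L
      if (words >= cap) break
    }
    c(lo, i)
  } else {
    hi <- occ$token_start[[1]]  # scope ends just before the trigger
    i <- hi
    words <- 0
    while (i > 0L) {
      if (stop_tok[[i]]) break
      if (!is_punct_token(toks$surface[[i]])) {
        words <- words + 1
      }
      i <- i - 1L
      if (words >= cap) break
    }
    c(i, hi)
  }
}

property_field <- function(property) {
  switch(property,
         negation = "negation",
         historical = "temporality",
         hypothetical = "temporality",
         experiencer = "experiencer")
}

property_value <- function(property) {
  switch(property,
         negation = "Negated",
         historical = "Historical",
         hypothetical = "Hypothetical",
         experiencer = "Other")
}

value_field <- function(value) {
  switch(value,
         Negated = "negation", NotNegated = "negation",
         Recent = "temporality", Historical = "temporality",
         Hypothetical = "temporality",
         Patient = "experiencer", Other = "experiencer",
         stop("unknown property value '", value, "'"))
}

evidence_row <- function(property, phrase_or_rule, char_start = NA_integer_,
                         char_end = NA_integer_) {
  data.frame(property = property, phrase_or_rule = phrase_or_rule,
             char_start = as.integer(char_start),
             char_end = as.integer(char_end), stringsAsFactors = FALSE)
}

empty_evidence <- function() {
  data.frame(property = character(), phrase_or_rule = character(),
             char_start = integer(), char_end = integer(),
             stringsAsFactors = FALSE)
}

# Overwrite semantics: a later assignment to the same annotation field
# replaces both the value and the evidence for that field.
set_value <- function(ann, i, field, value, evidence) {
  ann$values[[field]][[i]] <- value
  ev <- ann$evidence[[i]]
  if (nrow(ev)) {
    same_field <- vapply(ev$property, property_field, character(1)) == field
    ev <- ev[!same_field, , drop = FALSE]
  }
  ann$evidence[[i]] <- rbind(ev, evidence)
  ann
}

#' Assign contextual property values to marked concepts in a sentence
#'
#' The full per-sentence pipeline:
#' 1. every mention starts at the defaults NotNegated / Recent / Patient;
#' 2. trigger occurrences are processed left to right (pseudo skipped);
#'    a mention inside the resolved scope takes the trigger's value,
#'    later triggers of the same property overwriting earlier ones;
#' 3. the GP minus rule (when active) negates a mention immediately
#'    followed by a detached or attached minus sign;
#' 4. combined pre+post rules (when active) fire when both phrases
#'    surround the mention within their span gate;
#' 5. the temporality module runs last and may upgrade Recent to
#'    Historical.
#'
#' A mention overlapping a trigger occurrence is not eligible for that
#' trigger's value (guards against lexicon/term-list collisions).
#'
#' @param sent A `clinical_sentence`.
#' @param mentions Mentions from [match_concepts()].
#' @param lex A `trigger_lexicon`.
#' @param rules Combined-rule data frame or `NULL`.
#' @param profile A `document_profile`.
#' @param temporal_patterns Patterns for the temporality module, or
#'   `NULL` to skip the module.
#' @param reference_year Optional document reference year used by
#'   year-mention temporal patterns.
#' @return Data frame of class `context_annotations`: one row per
#'   mention with `negation`, `temporality`, `experiencer` and an
#'   `evidence` list-column.
#' @export
apply_context <- function(sent, mentions, lex,
                          rules = default_combined_rules(),
                          profile,
                          temporal_patterns = default_temporal_patterns(),
                          reference_year = NA_integer_) {
  stopifnot(inherits(sent, "clinical_sentence"),
            inherits(profile, "document_profile"))
  n_tok <- nrow(sent$tokens)
  nm <- nrow(mentions)
  if (nm > 0 && (any(mentions$token_start < 0) ||
                 any(mentions$token_end > n_tok))) {
    stop("mention outside sentence bounds")
  }
  ann <- list(
    values = list(negation = rep("NotNegated", nm),
                  temporality = rep("Recent", nm),
                  experiencer = rep("Patient", nm)),
    evidence = replicate(nm, empty_evidence(), simplify = FALSE))
  occ <- find_triggers(sent, lex, profile$doc_type)
  term_occ <- occ[occ$role == "termination", , drop = FALSE]
  active <- occ[occ$role %in% c("pre", "post"), , drop = FALSE]
  for (i in seq_len(nrow(active))) {
    o <- active[i, , drop = FALSE]
    sc <- resolve_scope(o, sent, profile, term_occ)
    if (sc[[1]] >= sc[[2]]) next
    for (j in seq_len(nm)) {
      inside <- mentions$token_start[[j]] < sc[[2]] &&
        mentions$token_end[[j]] > sc[[1]]
      overlaps_trigger <- mentions$token_start[[j]] < o$token_end[[1]] &&
        mentions$token_end[[j]] > o$token_start[[1]]
      if (inside && !overlaps_trigger) {
        ann <- set_value(ann, j, property_field(o$property[[1]]),
                         property_value(o$property[[1]]),
                         evidence_row(o$property[[1]], o$phrase[[1]],
                                      o$char_start[[1]], o$char_end[[1]]))
      }
    }
  }
  if (profile$gp_minus_rule_active) {
    ann <- apply_gp_minus_rule_impl(sent, mentions, ann)
  }
  if (profile$combined_rules_active && !is.null(rules) && nrow(rules) > 0) {
    ann <- apply_combined_rules_impl(sent, mentions, rules, profile, ann)
  }
  if (!is.null(temporal_patterns)) {
    for (j in seq_len(nm)) {
      if (ann$values$temporality[[j]] != "Recent") next
      det <- detect_historical(sent, mentions[j, , drop = FALSE],
                               temporal_patterns, reference_year)
      if (det$historical) {
        ann <- set_value(ann, j, "temporality", "Historical",
                         evidence_row("historical",
                                      paste0("temporal:", det$pattern_ids[[1]])))
      }
    }
  }
  out <- data.frame(term = if (nm) mentions$term else character(),
                    char_start = if (nm) mentions$char_start else integer(),
                    char_end = if (nm) mentions$char_end else integer(),
                    negation = ann$values$negation,
                    temporality = ann$values$temporality,
                    experiencer = ann$values$experiencer,
                    stringsAsFactors = FALSE)
  out$evidence <- ann$evidence
  out$doc_id <- rep(sent$doc_id, nm)
  out$sentence_index <- rep(sent$index_in_doc, nm)
  class(out) <- c("context_annotations", "data.frame")
  out
}

# The GP minus rule: "koorts-" or "koorts -" followed by whitespace,
# punctuation or the sentence end negates the mention.  A hyphen that
# joins a following word ("koorts-achtig") does not count.
apply_gp_minus_rule_impl <- function(sent, mentions, ann) {
  txt <- sent$text
  n <- nchar(txt)
  for (j in seq_len(nrow(mentions))) {
    pos <- mentions$char_end[[j]]  # 0-based offset just past the mention
    if (pos < n && substring(txt, pos + 1L, pos + 1L) == " ") pos <- pos + 1L
    if (pos >= n || substring(txt, pos + 1L, pos + 1L) != "-") next
    nxt <- if (pos + 1L >= n) "" else substring(txt, pos + 2L, pos + 2L)
    if (nxt == "" || grepl("[ \t\r\n]", nxt) || nxt %in% PUNCT_CHARS) {
      ann <- set_value(ann, j, "negation", "Negated",
                       evidence_row("negation", "gp-minus",
                                    pos, pos + 1L))
    }
  }
  ann
}

apply_combined_rules_impl <- function(sent, mentions, rules, profile, ann) {
  toks_lower <- tolower(sent$tokens$surface)
  rules <- rules[doc_types_match(rules$doc_types, profile$doc_type), ,
                 drop = FALSE]
  for (r in seq_len(nrow(rules))) {
    pre_t <- phrase_tokens(rules$pre_phrase[[r]])
    post_t <- phrase_tokens(rules$post_phrase[[r]])
    pre_occ <- scan_phrase(toks_lower, pre_t)
    post_occ <- scan_phrase(toks_lower, post_t)
    if (length(pre_occ) == 0 || length(post_occ) == 0) next
    for (j in seq_len(nrow(mentions))) {
      ts <- mentions$token_start[[j]]
      te <- mentions$token_end[[j]]
      for (p1 in pre_occ) {
        if (p1 + length(pre_t) > ts) next
        for (p2 in post_occ) {
          if (p2 < te) next
          span <- (p2 + length(post_t)) - p1
          if (span > rules$max_span_tokens[[r]]) next
          toks <- sent$tokens
          ev <- rbind(
            evidence_row(rules$property[[r]], rules$pre_phrase[[r]],
                         toks$start[[p1 + 1L]],
                         toks$end[[p1 + length(pre_t)]]),
            evidence_row(rules$property[[r]], rules$post_phrase[[r]],
                         toks$start[[p2 + 1L]],
                         toks$end[[p2 + length(post_t)]]))
          ann <- set_value(ann, j, value_field(rules$value[[r]]),
                           rules$value[[r]], ev)
        }
      }
    }
  }
  ann
}
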