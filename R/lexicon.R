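# Trigger lexicon: the rule base of the ConText-family algorithm.
#
# Four trigger roles per contextual property:
#   pre         -- precedes the concept, scope extends rightwards
#   post        -- follows the concept, scope extends leftwards
#   pseudo      -- looks like a trigger but must not fire (masks lookalikes)
#   termination -- cuts a running scope short

#' Contextual properties handled by the annotator
#' @export
CONTEXT_PROPERTIES <- c("negation", "historical", "hypothetical", "experiencer")

#' Trigger roles
#' @export
TRIGGER_ROLES <- c("pre", "post", "pseudo", "termination")

#' Supported clinical document types
#'
#' GP = general practitioner entries, SP = specialist letters,
#' RD = radiology reports, DL = discharge letters.
#' @export
DOC_TYPES <- c("GP", "SP", "RD", "DL")

LEXICON_COLUMNS <- c("phrase", "property", "role", "doc_types",
                     "max_scope_tokens", "note")
COMBINED_COLUMNS <- c("pre_phrase", "post_phrase", "property", "value",
                      "max_span_tokens", "doc_types")

normalize_phrase <- function(x) tolower(trimws(x))

parse_doc_types <- function(x) {
  x <- trimws(x)
  if (x == "" || x == "*") return("*")
  parts <- toupper(trimws(strsplit(x, ",", fixed = TRUE)[[1]]))
  bad <- setdiff(parts, DOC_TYPES)
  if (length(bad)) stop("unknown doc_type '", bad[[1]], "'", call. = FALSE)
  paste(parts, collapse = ",")
}

doc_types_match <- function(doc_types, doc_type) {
  doc_types == "*" | vapply(strsplit(doc_types, ",", fixed = TRUE),
                            function(p) doc_type %in% p, logical(1))
}

#' Construct a single trigger entry
#'
#' @param phrase Trigger phrase; stored lowercase, one or more
#'   whitespace-separated tokens.
#' @param property One of `CONTEXT_PROPERTIES`.
#' @param role One of `TRIGGER_ROLES`.
#' @param doc_types Character vector, subset of `DOC_TYPES`; empty means
#'   applicable to all document types.
#' @param max_scope_tokens Optional positive integer overriding the
#'   document profile's default scope length for this entry.
#' @param note Free-text provenance note.
#' @return One-row data frame with the lexicon schema.
#' @export
trigger_entry <- function(phrase, property, role, doc_types = character(),
                          max_scope_tokens = NA_integer_, note = "") {
  phrase <- normalize_phrase(phrase)
  if (!nzchar(phrase)) stop("trigger phrase must be non-empty")
  property <- match.arg(property, CONTEXT_PROPERTIES)
  role <- match.arg(role, TRIGGER_ROLES)
  if (!is.na(max_scope_tokens)) {
    max_scope_tokens <- as.integer(max_scope_tokens)
    if (max_scope_tokens < 1L) stop("max_scope_tokens must be >= 1")
  }
  dt <- if (length(doc_types) == 0) "*" else
    parse_doc_types(paste(doc_types, collapse = ","))
  data.frame(phrase = phrase, property = property, role = role,
             doc_types = dt,
             max_scope_tokens = as.integer(max_scope_tokens),
             note = note, stringsAsFactors = FALSE)
}

#' Construct a trigger lexicon
#'
#' @param entries Data frame of trigger entries (rows as produced by
#'   [trigger_entry()], possibly `rbind`-ed).
#' @param version Free-text lexicon version label.
#' @param language ISO language code, default `"nl"`.
#' @return Object of class `trigger_lexicon`.
#' @export
trigger_lexicon <- function(entries, version = "custom", language = "nl") {
  stopifnot(is.data.frame(entries), all(LEXICON_COLUMNS %in% names(entries)))
  entries <- entries[, LEXICON_COLUMNS]
  entries$phrase <- vapply(entries$phrase, normalize_phrase, character(1),
                           USE.NAMES = FALSE)
  key <- paste(entries$phrase, entries$property, entries$role, sep = "\r")
  if (anyDuplicated(key)) {
    d <- entries$phrase[duplicated(key)][[1]]
    stop("duplicate lexicon entry for phrase '", d, "'")
  }
  structure(list(entries = entries, version = version, language = language),
            class = "trigger_lexicon")
}

#' @export
print.trigger_lexicon <- function(x, ...) {
  cat("<trigger_lexicon> version:", x$version,
      " language:", x$language, "\n")
  print(lexicon_counts(x))
  invisible(x)
}

#' Entry counts per contextual property
#'
#' @param lex A `trigger_lexicon`.
#' @return Data frame with columns `property`, `role`, `n`.
#' @export
lexicon_counts <- function(lex) {
  e <- lex$entries
  agg <- as.data.frame(table(property = e$property, role = e$role),
                       stringsAsFactors = FALSE)
  names(agg)[3] <- "n"
  agg <- agg[agg$n > 0, ]
  rownames(agg) <- NULL
  agg
}

#' Read a trigger lexicon from a TSV file
#'
#' Expected header: `phrase  property  role  doc_types  max_scope_tokens
#' note`.  `doc_types` is a comma-joined subset of `DOC_TYPES` or `"*"`.
#'
#' @param path Path to a UTF-8 tab-separated file.
#' @param version Version label for the returned lexicon.
#' @return A `trigger_lexicon`.
#' @export
read_lexicon <- function(path, version = basename(path)) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(raw) == 0) stop("lexicon file is empty (no header): ", path)
  header <- strsplit(raw[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header, LEXICON_COLUMNS)) {
    stop("lexicon header must be: ", paste(LEXICON_COLUMNS, collapse = ", "))
  }
  body <- raw[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) {
    warning("lexicon file has no entries: ", path)
    e <- data.frame(phrase = character(), property = character(),
                    role = character(), doc_types = character(),
                    max_scope_tokens = integer(), note = character(),
                    stringsAsFactors = FALSE)
    return(trigger_lexicon(e, version = version))
  }
  rows <- lapply(seq_along(body), function(i) {
    line_no <- i + 1L
    f <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4 || length(f) > 6) {
      stop("malformed row at line ", line_no, ": expected 4-6 fields, got ",
           length(f))
    }
    f <- c(f, rep("", 6 - length(f)))
    if (!f[[2]] %in% CONTEXT_PROPERTIES) {
      stop("unknown property '", f[[2]], "' at line ", line_no)
    }
    if (!f[[3]] %in% TRIGGER_ROLES) {
      stop("unknown role '", f[[3]], "' at line ", line_no)
    }
    mst <- trimws(f[[4 + 1]])
    mst <- if (mst == "") NA_integer_ else suppressWarnings(as.integer(mst))
    if (!is.na(f[[5]]) && nzchar(trimws(f[[5]])) && is.na(mst)) {
      stop("invalid max_scope_tokens '", f[[5]], "' at line ", line_no)
    }
    if (!is.na(mst) && mst < 1L) {
      stop("max_scope_tokens must be >= 1 at line ", line_no)
    }
    dt <- tryCatch(parse_doc_types(f[[4]]), error = function(e) {
      stop(conditionMessage(e), " at line ", line_no, call. = FALSE)
    })
    data.frame(phrase = normalize_phrase(f[[1]]), property = f[[2]],
               role = f[[3]], doc_types = dt, max_scope_tokens = mst,
               note = f[[6]], stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, rows)
  key <- paste(entries$phrase, entries$property, entries$role, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[[1]]
    stop("duplicate (phrase, property, role) row at line ", i + 1L, ": '",
         entries$phrase[[i]], "'")
  }
  trigger_lexicon(entries, version = version)
}

#' Write a trigger lexicon to TSV
#'
#' Round-trips with [read_lexicon()].
#'
#' @param lex A `trigger_lexicon`.
#' @param path Output path.
#' @export
write_lexicon <- function(lex, path) {
  e <- lex$entries
  mst <- ifelse(is.na(e$max_scope_tokens), "", as.character(e$max_scope_tokens))
  lines <- c(paste(LEXICON_COLUMNS, collapse = "\t"),
             paste(e$phrase, e$property, e$role, e$doc_types, mst, e$note,
                   sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Validate a trigger lexicon
#'
#' Emits one diagnostic string per problem found:
#' * a pseudo entry whose phrase does not contain any non-pseudo phrase of
#'   the same property as a substring (a pseudo trigger exists to mask a
#'   lookalike, so a counterpart must exist);
#' * a phrase containing characters outside letters/digits/space/hyphen/
#'   period, or irregular whitespace.
#'
#' @param lex A `trigger_lexicon`.
#' @return Character vector of diagnostics (empty when clean).
#' @export
validate_lexicon <- function(lex) {
  e <- lex$entries
  out <- character()
  for (i in seq_len(nrow(e))) {
    ph <- e$phrase[[i]]
    if (grepl("[^\\p{L}\\p{N} .-]", ph, perl = TRUE) || grepl("  ", ph)) {
      out <- c(out, paste0("phrase '", ph,
                           "' contains characters outside letters/digits/",
                           "space/hyphen/period or irregular whitespace"))
    }
    if (e$role[[i]] == "pseudo") {
      others <- e$phrase[e$property == e$property[[i]] & e$role != "pseudo"]
      masked <- any(vapply(others, function(o) grepl(o, ph, fixed = TRUE),
                           logical(1)))
      if (!masked) {
        out <- c(out, paste0("pseudo trigger '", ph, "' (", e$property[[i]],
                             ") masks no non-pseudo trigger of the same ",
                             "property"))
      }
    }
  }
  out
}

#' Expand a base trigger into Dutch variant entries
#'
#' Several English triggers have no single Dutch equivalent; each variant
#' becomes its own entry sharing property/role/doc_types, with a
#' provenance note recording the base phrase.
#'
#' @param base_phrase The source phrase (recorded in the note).
#' @param variants Character vector of variant phrases.
#' @inheritParams trigger_entry
#' @return Data frame of entries, duplicates collapsed with a warning.
#' @export
expand_variants <- function(base_phrase, variants, property, role,
                            doc_types = character()) {
  stopifnot(nzchar(base_phrase), length(variants) >= 1,
            all(nzchar(variants)))
  variants <- vapply(variants, normalize_phrase, character(1),
                     USE.NAMES = FALSE)
  if (anyDuplicated(variants)) {
    warning("duplicate variants collapsed for base '", base_phrase, "'")
    variants <- unique(variants)
  }
  do.call(rbind, lapply(variants, function(v) {
    trigger_entry(v, property, role, doc_types,
                  note = paste0("variant of '", base_phrase, "'"))
  }))
}

#' Construct a combined-trigger rule
#'
#' A combined rule asserts a property value only when a pre phrase occurs
#' before the concept and a post phrase after it, within a bounded token
#' span.  The canonical example is the pre/post pair "nooit" ...
#' "doorgemaakt" surrounding a condition, which together negate it while
#' neither phrase is reliable alone.
#'
#' @param pre_phrase,post_phrase The two phrases (distinct).
#' @param property One of `CONTEXT_PROPERTIES`.
#' @param value The property value asserted (e.g. `"Negated"`).
#' @param max_span_tokens Maximum token span from the start of the pre
#'   occurrence to the end of the post occurrence.
#' @param doc_types Subset of `DOC_TYPES`; empty = all.
#' @return One-row data frame with the combined-rule schema.
#' @export
combined_rule <- function(pre_phrase, post_phrase, property, value,
                          max_span_tokens = 10L, doc_types = character()) {
  pre_phrase <- normalize_phrase(pre_phrase)
  post_phrase <- normalize_phrase(post_phrase)
  if (identical(pre_phrase, post_phrase)) {
    stop("pre_phrase and post_phrase must differ")
  }
  property <- match.arg(property, CONTEXT_PROPERTIES)
  max_span_tokens <- as.integer(max_span_tokens)
  if (max_span_tokens < 1L) stop("max_span_tokens must be >= 1")
  dt <- if (length(doc_types) == 0) "*" else
    parse_doc_types(paste(doc_types, collapse = ","))
  data.frame(pre_phrase = pre_phrase, post_phrase = post_phrase,
             property = property, value = value,
             max_span_tokens = max_span_tokens, doc_types = dt,
             stringsAsFactors = FALSE)
}

#' Read combined-trigger rules from TSV
#'
#' Header: `pre_phrase  post_phrase  property  value  max_span_tokens
#' doc_types`.
#'
#' @param path Path to a UTF-8 TSV file.
#' @return Data frame of combined rules.
#' @export
read_combined_rules <- function(path) {
  if (!file.exists(path)) stop("combined-rules file not found: ", path)
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  header <- strsplit(raw[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header, COMBINED_COLUMNS)) {
    stop("combined-rules header must be: ",
         paste(COMBINED_COLUMNS, collapse = ", "))
  }
  body <- raw[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) return(empty_combined_rules())
  do.call(rbind, lapply(seq_along(body), function(i) {
    f <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5) stop("malformed combined rule at line ", i + 1L)
    f <- c(f, rep("", 6 - length(f)))
    combined_rule(f[[1]], f[[2]], f[[3]], f[[4]],
                  as.integer(f[[5]]),
                  if (trimws(f[[6]]) %in% c("", "*")) character() else
                    strsplit(f[[6]], ",", fixed = TRUE)[[1]])
  }))
}

#' Write combined-trigger rules to TSV
#' @param rules Data frame of combined rules.
#' @param path Output path.
#' @export
write_combined_rules <- function(rules, path) {
  lines <- c(paste(COMBINED_COLUMNS, collapse = "\t"),
             if (nrow(rules)) paste(rules$pre_phrase, rules$post_phrase,
                                    rules$property, rules$value,
                                    rules$max_span_tokens, rules$doc_types,
                                    sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

empty_combined_rules <- function() {
  data.frame(pre_phrase = character(), post_phrase = character(),
             property = character(), value = character(),
             max_span_tokens = integer(), doc_types = character(),
             stringsAsFactors = FALSE)
}

#' The bundled Dutch trigger lexicon
#'
#' Two configurations are shipped:
#' * `"paper-final"` -- the conservative production list: no bare "nooit"
#'   pre-trigger (unreliable alone; covered by a combined rule instead),
#'   no "bij", and no ambiguous experiencer abbreviations ("pa", "oma").
#' * `"extended"` -- additionally includes phrases suggested by error
#'   analysis on clinical text: "blanco voor", the ": nee" short-scope
#'   post-trigger, and the hypothetical pre-trigger "bij".
#'
#' The list is deliberately compact and fully user-replaceable: the
#' algorithm's contract is its behavior given a lexicon, not a specific
#' inventory.
#'
#' @param profile `"paper-final"` (default) or `"extended"`.
#' @return A `trigger_lexicon`.
#' @export
default_lexicon <- function(profile = c("paper-final", "extended")) {
  profile <- match.arg(profile)
  te <- trigger_entry
  core <- rbind(
    # negation pre-triggers
    te("geen", "negation", "pre"),
    te("geen teken van", "negation", "pre"),
    te("geen aanwijzing voor", "negation", "pre"),
    te("geen aanwijzingen voor", "negation", "pre"),
    te("niet", "negation", "pre"),
    te("zonder", "negation", "pre"),
    te("sluit uit", "negation", "pre"),
    expand_variants("never had", c("had nooit", "hadden nooit"),
                    "negation", "pre"),
    # negation post-triggers
    expand_variants("never had", "nooit gehad", "negation", "post"),
    te("uitgesloten", "negation", "post"),
    te("afwezig", "negation", "post"),
    te("niet aangetoond", "negation", "post"),
    # pseudo triggers: mask lookalikes of the above
    te("niet minder", "negation", "pseudo",
       note = "masks 'niet'; 'no fewer' is not a negation"),
    te("niet uitgesloten", "negation", "pseudo",
       note = "double negation: 'not ruled out'"),
    te("geen toename", "negation", "pseudo",
       note = "'no increase' does not negate the condition"),
    # termination triggers for negation scopes
    te("maar", "negation", "termination"),
    te("echter", "negation", "termination"),
    te("behalve", "negation", "termination"),
    # temporality: historical
    te("status na", "historical", "pre"),
    te("st. na", "historical", "pre"),
    te("doorgemaakte", "historical", "pre"),
    te("in de voorgeschiedenis", "historical", "post"),
    te("in het verleden", "historical", "post"),
    # temporality: hypothetical
    te("indien", "hypothetical", "pre"),
    te("tenzij", "hypothetical", "pre"),
    te("risico op", "hypothetical", "pre"),
    te("ter preventie van", "hypothetical", "pre"),
    # experiencer: anyone but the patient; ambiguous abbreviations
    # ("pa" = dad/pathology, "oma" = grandmother/otitis media acuta)
    # are intentionally absent
    te("moeder", "experiencer", "pre"),
    te("vader", "experiencer", "pre"),
    te("broer", "experiencer", "pre"),
    te("zus", "experiencer", "pre"),
    te("familieanamnese", "experiencer", "pre"),
    te("in de familie", "experiencer", "post")
  )
  if (profile == "extended") {
    core <- rbind(core,
      te("blanco voor", "negation", "pre",
         note = "'blank (family history) for'"),
      te(": nee", "negation", "post", max_scope_tokens = 2L,
         note = "checklist answer 'no'; short scope"),
      te("bij", "hypothetical", "pre",
         note = "'upon'; extended list only"))
  }
  trigger_lexicon(core, version = paste0("contextnl-", profile))
}

#' The bundled combined-trigger rules
#'
#' @return Data frame of combined rules (currently the "nooit ...
#'   doorgemaakt" negation pair).
#' @export
default_combined_rules <- function() {
  combined_rule("nooit", "doorgemaakt", "negation", "Negated",
                max_span_tokens = 10L)
}
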