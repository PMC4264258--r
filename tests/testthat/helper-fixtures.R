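# Shared helpers: tiny lexicons and hand-built inputs used across the
# unit suites.  Fixtures are constructed in code, never read from disk.

mini_lexicon <- function(extra = NULL) {
  e <- rbind(
    trigger_entry("geen", "negation", "pre"),
    trigger_entry("niet", "negation", "pre"),
    trigger_entry("niet minder", "negation", "pseudo"),
    trigger_entry("uitgesloten", "negation", "post"),
    trigger_entry("maar", "negation", "termination"),
    trigger_entry("status na", "historical", "pre"),
    trigger_entry("indien", "hypothetical", "pre"),
    trigger_entry("moeder", "experiencer", "pre"))
  if (!is.null(extra)) e <- rbind(e, extra)
  trigger_lexicon(e, version = "mini")
}

# A lexicon with no entries: used for default-preservation checks.
empty_lexicon <- function() {
  e <- mini_lexicon()$entries[0, ]
  trigger_lexicon(e, version = "empty")
}

write_lexicon_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(c("phrase\tproperty\trole\tdoc_types\tmax_scope_tokens\tnote",
               lines), path, useBytes = TRUE)
  path
}

# Hand-marked mention for a term occupying given token interval.
manual_mention <- function(term, char_start, char_end, token_start,
                           token_end) {
  data.frame(term = term, char_start = as.integer(char_start),
             char_end = as.integer(char_end),
             token_start = as.integer(token_start),
             token_end = as.integer(token_end),
             concept_id = NA_character_, stringsAsFactors = FALSE)
}

# Annotate one sentence with the bundled configuration and return the
# single annotation row.
annotate_one <- function(text, term, doc_type,
                         lex = default_lexicon(),
                         rules = default_combined_rules(),
                         patterns = default_temporal_patterns()) {
  s <- sentence(text)
  m <- match_concepts(s, term)
  stopifnot(nrow(m) == 1)
  apply_context(s, m, lex, rules, document_profile(doc_type), patterns)
}

# Minimal gold/pred annotation frames for the evaluation module.
label_frame <- function(negation, temporality = NULL, experiencer = NULL,
                        doc_type = "GP") {
  n <- length(negation)
  data.frame(doc_id = sprintf("d%02d", seq_len(n)), sentence_index = 0L,
             char_start = 0L, char_end = 5L, term = "t",
             doc_type = doc_type,
             negation = negation,
             temporality = if (is.null(temporality)) rep("Recent", n)
                           else temporality,
             experiencer = if (is.null(experiencer)) rep("Patient", n)
                           else experiencer,
             stringsAsFactors = FALSE)
}
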