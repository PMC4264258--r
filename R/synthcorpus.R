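# Synthetic annotated-corpus generator: a deterministic stand-in for a
# protected clinical corpus.  Sentences are realized from templates
# whose semantics define the gold labels; the engine is never consulted
# when assigning gold (that would make round-trip tests circular).

#' Neutral Dutch filler vocabulary
#'
#' Deliberately disjoint from the bundled trigger phrases, combined-rule
#' phrases, temporal-pattern vocabulary and the default term list, so a
#' filler can never accidentally fire a rule or become a mention.
#' @return Character vector of words.
#' @export
filler_vocabulary <- function() {
  c("verder", "hierbij", "overleg", "controle", "rustig", "verloop",
    "gesproken", "samen", "afspraak", "uitleg", "gegeven", "besproken",
    "telefonisch", "consult", "vervolg", "beleid", "conform", "stabiel",
    "ongewijzigd", "voortzetten", "heden", "aanwezig", "gezien",
    "beoordeeld", "het", "de", "een", "en", "is", "heeft")
}

#' Default synthetic term list
#'
#' Plays the role of a medical term list for generated corpora.
#' @return Character vector of Dutch condition terms.
#' @export
default_term_list <- function() {
  c("koorts", "hoest", "sinusitis", "pneumonie", "appendicitis",
    "diabetes", "hypertensie", "urineweginfecties", "trombose",
    "kanker", "tinnitus", "krampen", "hoofdpijn", "influenza",
    "niersteen", "appendectomie", "dyspnoe", "otitis", "eczeem",
    "migraine")
}

#' Construct a template specification
#'
#' Slots (space-separated descriptors, realized left to right):
#' * `LIT:<text>`  -- literal token(s), underscores become spaces
#' * `FILLER:<k>`  -- k words sampled from the filler vocabulary
#' * `CONCEPT`     -- the single concept mention (term sampled per use)
#' * `MINUS`       -- a minus sign attached to the preceding token
#' * `TERM:<tok>`  -- a literal terminator token such as `,`
#'
#' @param template_id Unique identifier.
#' @param doc_type One of `DOC_TYPES`.
#' @param slots Character vector of slot descriptors; exactly one
#'   `CONCEPT`.
#' @param gold Named character vector with `negation`, `temporality`,
#'   `experiencer`.
#' @param engine_consistent Whether the bundled paper-final
#'   configuration is expected to recover the gold labels.
#' @return One-row data frame (slots and gold stored as list-columns).
#' @export
template_spec <- function(template_id, doc_type, slots, gold,
                          engine_consistent = TRUE) {
  doc_type <- match.arg(doc_type, DOC_TYPES)
  if (sum(slots == "CONCEPT") != 1) {
    stop("template '", template_id, "' must have exactly one CONCEPT slot")
  }
  stopifnot(all(c("negation", "temporality", "experiencer") %in%
                  names(gold)))
  out <- data.frame(template_id = template_id, doc_type = doc_type,
                    engine_consistent = engine_consistent,
                    stringsAsFactors = FALSE)
  out$slots <- list(slots)
  out$gold <- list(gold[c("negation", "temporality", "experiencer")])
  out
}

gold_class <- function(gold) {
  if (gold[["negation"]] == "Negated") "negated"
  else if (gold[["temporality"]] == "Historical") "historical"
  else if (gold[["temporality"]] == "Hypothetical") "hypothetical"
  else if (gold[["experiencer"]] == "Other") "other"
  else "default"
}

default_gold <- function(negation = "NotNegated", temporality = "Recent",
                         experiencer = "Patient") {
  c(negation = negation, temporality = temporality,
    experiencer = experiencer)
}

#' Bundled engine-consistent templates
#'
#' Covers every (property value, document type) combination present in
#' the default class mixture, through every rule path: plain
#' pre-/post-triggers, the GP minus rule, the combined pre+post rule,
#' lexicon and regex historical evidence, hypothetical and experiencer
#' triggers, and all-default sentences.  Discharge letters carry no
#' hypothetical template, matching their observed 0% share.
#'
#' @return Data frame of template specifications.
#' @export
default_templates <- function() {
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- template_spec(...)
  for (dt in DOC_TYPES) {
    add(paste0("neg-geen-", dt), dt,
        c("LIT:geen", "FILLER:1", "CONCEPT"),
        default_gold(negation = "Negated"))
    add(paste0("neg-post-", dt), dt,
        c("CONCEPT", "LIT:uitgesloten"),
        default_gold(negation = "Negated"))
    add(paste0("neg-combined-", dt), dt,
        c("LIT:nooit", "CONCEPT", "LIT:doorgemaakt"),
        default_gold(negation = "Negated"))
    add(paste0("hist-statusna-", dt), dt,
        c("LIT:status_na", "CONCEPT"),
        default_gold(temporality = "Historical"))
    add(paste0("hist-geleden-", dt), dt,
        c("LIT:3_jaar_geleden", "CONCEPT", "FILLER:1"),
        default_gold(temporality = "Historical"))
    if (dt != "DL") {
      add(paste0("hyp-indien-", dt), dt,
          c("LIT:indien", "CONCEPT", "FILLER:1"),
          default_gold(temporality = "Hypothetical"))
    }
    add(paste0("exp-moeder-", dt), dt,
        c("LIT:moeder", "LIT:heeft", "CONCEPT"),
        default_gold(experiencer = "Other"))
    add(paste0("default-", dt), dt,
        c("FILLER:2", "CONCEPT", "FILLER:1"),
        default_gold())
  }
  add("neg-minus-GP", "GP", c("CONCEPT", "MINUS", "FILLER:2"),
      default_gold(negation = "Negated"))
  do.call(rbind, rows)
}

#' Adversarial templates reproducing documented failure modes
#'
#' Gold labels follow the template semantics; `engine_consistent`
#' records whether the bundled paper-final configuration recovers them:
#' * missing triggers (": nee" checklist answers, "blanco voor",
#'   "is weg") -- gold Negated, engine misses them;
#' * pseudo-trigger sentences ("niet minder") -- gold NotNegated,
#'   recovered only because the pseudo list is shipped;
#' * out-of-scope placement (filler beyond the 6-word GP scope) and
#'   terminator interposition -- gold NotNegated;
#' * a relational-operator duration ("als <3 weken niet beter") that the
#'   temporal guard must veto -- gold Recent.
#'
#' @return Data frame of template specifications.
#' @export
adversarial_suite <- function() {
  rows <- list(
    template_spec("adv-colon-nee", "GP",
                  c("CONCEPT", "TERM::", "LIT:nee"),
                  default_gold(negation = "Negated"),
                  engine_consistent = FALSE),
    template_spec("adv-blanco-voor", "GP",
                  c("LIT:blanco_voor", "CONCEPT"),
                  default_gold(negation = "Negated"),
                  engine_consistent = FALSE),
    template_spec("adv-is-weg", "SP",
                  c("CONCEPT", "LIT:is_weg"),
                  default_gold(negation = "Negated"),
                  engine_consistent = FALSE),
    template_spec("adv-pseudo-niet-minder", "GP",
                  c("LIT:niet_minder", "CONCEPT"),
                  default_gold(),
                  engine_consistent = TRUE),
    template_spec("adv-out-of-scope", "GP",
                  c("LIT:geen", "FILLER:8", "CONCEPT"),
                  default_gold(),
                  engine_consistent = TRUE),
    template_spec("adv-terminator", "GP",
                  c("LIT:geen", "FILLER:1", "TERM:,", "CONCEPT"),
                  default_gold(),
                  engine_consistent = TRUE),
    template_spec("adv-temporal-guard", "GP",
                  c("LIT:net", "CONCEPT", "LIT:gehad", "LIT:als",
                    "LIT:<3_weken", "LIT:niet_beter"),
                  default_gold(),
                  engine_consistent = TRUE))
  do.call(rbind, rows)
}

#' Default class-mixture configuration
#'
#' Per-document-type fractions of negated / historical / hypothetical /
#' experiencer-Other mentions, mirroring the observed distribution in
#' annotated Dutch clinical text: GP 12/2/1/2%, SP 15/8/2/1%,
#' RD 16/3/1/0.1%, DL 13/6/0/2%.
#'
#' @param n Mentions generated per document type.
#' @param seed Integer seed.
#' @return List of class `mixture_config`.
#' @export
default_mixture <- function(n = 1000L, seed = 42L) {
  mix <- list(
    GP = c(negated = 0.12, historical = 0.02, hypothetical = 0.01,
           other = 0.02),
    SP = c(negated = 0.15, historical = 0.08, hypothetical = 0.02,
           other = 0.01),
    RD = c(negated = 0.16, historical = 0.03, hypothetical = 0.01,
           other = 0.001),
    DL = c(negated = 0.13, historical = 0.06, hypothetical = 0.00,
           other = 0.02))
  mixture_config(mix, n = n, seed = seed)
}

#' Construct a mixture configuration
#'
#' @param fractions Named list (per doc type) of named fraction vectors
#'   with entries `negated`, `historical`, `hypothetical`, `other`.
#' @param n Mentions per document type.
#' @param seed Integer seed.
#' @return List of class `mixture_config`.
#' @export
mixture_config <- function(fractions, n = 1000L, seed = 42L) {
  stopifnot(all(names(fractions) %in% DOC_TYPES))
  for (dt in names(fractions)) {
    f <- fractions[[dt]]
    stopifnot(all(c("negated", "historical", "hypothetical", "other") %in%
                    names(f)), all(f >= 0 & f <= 1), sum(f) <= 1)
  }
  structure(list(fractions = fractions, n = as.integer(n),
                 seed = as.integer(seed)), class = "mixture_config")
}

realize_template <- function(tmpl, terms, fillers) {
  slots <- tmpl$slots[[1]]
  words <- character()
  concept_idx <- NA_integer_
  for (s in slots) {
    if (s == "CONCEPT") {
      term <- sample(terms, 1L)
      words <- c(words, term)
      concept_idx <- length(words)
    } else if (s == "MINUS") {
      words[[length(words)]] <- paste0(words[[length(words)]], "-")
    } else if (startsWith(s, "FILLER:")) {
      k <- as.integer(sub("FILLER:", "", s))
      words <- c(words, sample(fillers, k, replace = TRUE))
    } else if (startsWith(s, "LIT:")) {
      words <- c(words, gsub("_", " ", sub("LIT:", "", s)))
    } else if (startsWith(s, "TERM:")) {
      words <- c(words, sub("TERM:", "", s))
    } else {
      stop("unknown slot descriptor '", s, "'")
    }
  }
  # sentence-case the first character, as real prose would have it
  text <- paste(words, collapse = " ")
  substring(text, 1, 1) <- toupper(substring(text, 1, 1))
  # concept character span: cumulative word offsets
  starts <- cumsum(c(0L, nchar(words) + 1L))
  cs <- starts[[concept_idx]]
  term <- words[[concept_idx]]
  ce <- cs + nchar(sub("-$", "", term))
  list(text = text, term = sub("-$", "", term), char_start = cs,
       char_end = ce)
}

#' Realize every template a fixed number of times
#'
#' Deterministic small-corpus builder for targeted tests and ablations:
#' each template is realized `reps` times, one sentence per document.
#'
#' @param templates Template data frame.
#' @param reps Realizations per template.
#' @param terms Term vector for concept slots.
#' @param seed Integer seed.
#' @return List with `documents` and `gold`, as [generate_corpus()].
#' @export
template_corpus <- function(templates, reps = 3L,
                            terms = default_term_list(), seed = 1L) {
  fillers <- filler_vocabulary()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  docs <- list()
  gold <- list()
  for (i in seq_len(nrow(templates))) {
    for (k in seq_len(reps)) {
      r <- realize_template(templates[i, , drop = FALSE], terms, fillers)
      doc_id <- sprintf("%s-%02d", templates$template_id[[i]], k)
      docs[[length(docs) + 1L]] <- data.frame(
        id = doc_id, doc_type = templates$doc_type[[i]],
        text = paste0(r$text, "."), stringsAsFactors = FALSE)
      g <- templates$gold[[i]]
      gold[[length(gold) + 1L]] <- data.frame(
        doc_id = doc_id, doc_type = templates$doc_type[[i]],
        sentence_index = 0L, term = r$term, char_start = r$char_start,
        char_end = r$char_end, negation = g[["negation"]],
        temporality = g[["temporality"]],
        experiencer = g[["experiencer"]],
        template_id = templates$template_id[[i]],
        engine_consistent = templates$engine_consistent[[i]],
        stringsAsFactors = FALSE)
    }
  }
  list(documents = do.call(rbind, docs), gold = do.call(rbind, gold))
}

#' Generate a synthetic corpus with gold annotations
#'
#' Quota sampling: each document type receives exactly
#' `round(fraction * n)` mentions of each non-default class (so small
#' corpora hit the requested mixture exactly), the remainder being
#' all-default sentences.  One sentence per mention; sentences are
#' packed into documents of `sentences_per_doc`.  Deterministic given
#' the seed.
#'
#' @param config A `mixture_config`.
#' @param templates Template data frame; defaults to the
#'   engine-consistent set.
#' @param terms Term vector used for concept slots.
#' @param sentences_per_doc Sentences packed per document.
#' @return List with `documents` (id, doc_type, text) and `gold`
#'   (annotation data frame with doc_type and template_id columns).
#' @export
generate_corpus <- function(config, templates = default_templates(),
                            terms = default_term_list(),
                            sentences_per_doc = 5L) {
  stopifnot(inherits(config, "mixture_config"))
  fillers <- filler_vocabulary()
  clash <- intersect(fillers, tolower(terms))
  if (length(clash)) {
    stop("filler vocabulary collides with term list: ",
         paste(clash, collapse = ", "))
  }
  tmpl_class <- vapply(seq_len(nrow(templates)), function(i) {
    gold_class(templates$gold[[i]])
  }, character(1))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  docs <- list()
  gold <- list()
  for (dt in names(config$fractions)) {
    f <- config$fractions[[dt]]
    counts <- c(round(f * config$n),
                default = config$n - sum(round(f * config$n)))
    plan <- character()
    for (cls in names(counts)) {
      if (counts[[cls]] == 0) next
      pool <- which(templates$doc_type == dt & tmpl_class == cls)
      if (length(pool) == 0) {
        stop("no template for class '", cls, "' in doc type '", dt, "'")
      }
      plan <- c(plan, sample(as.character(pool), counts[[cls]],
                             replace = TRUE))
    }
    # deterministic interleave of classes within the doc type
    plan <- sample(plan)
    sent_texts <- character(length(plan))
    sent_gold <- vector("list", length(plan))
    for (i in seq_along(plan)) {
      ti <- as.integer(plan[[i]])
      r <- realize_template(templates[ti, , drop = FALSE], terms, fillers)
      sent_texts[[i]] <- paste0(r$text, ".")
      g <- templates$gold[[ti]]
      sent_gold[[i]] <- data.frame(
        doc_type = dt, term = r$term, char_start = r$char_start,
        char_end = r$char_end, negation = g[["negation"]],
        temporality = g[["temporality"]],
        experiencer = g[["experiencer"]],
        template_id = templates$template_id[[ti]],
        engine_consistent = templates$engine_consistent[[ti]],
        stringsAsFactors = FALSE)
    }
    # pack into documents
    idx <- split(seq_along(plan),
                 ceiling(seq_along(plan) / sentences_per_doc))
    for (d in seq_along(idx)) {
      doc_id <- sprintf("%s-%04d", dt, d)
      texts <- sent_texts[idx[[d]]]
      docs[[length(docs) + 1L]] <- data.frame(
        id = doc_id, doc_type = dt,
        text = paste(texts, collapse = " "), stringsAsFactors = FALSE)
      for (k in seq_along(idx[[d]])) {
        g <- sent_gold[[idx[[d]][[k]]]]
        g$doc_id <- doc_id
        g$sentence_index <- k - 1L
        gold[[length(gold) + 1L]] <- g
      }
    }
  }
  list(documents = do.call(rbind, docs), gold = do.call(rbind, gold))
}
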