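# Trigger finding, scope resolution, context assignment, GP minus and
# combined rules.

test_that("find_triggers finds occurrences, longest-match, doc gating", {
  lex <- mini_lexicon(trigger_entry("geen teken van", "negation", "pre"))
  s <- sentence("er was geen teken van koorts")
  occ <- find_triggers(s, lex, "GP")
  # 'geen' is contained in 'geen teken van' (same property/role): dropped
  expect_equal(occ$phrase, "geen teken van")
  expect_equal(occ$token_start, 2)
  expect_equal(occ$token_end, 5)

  s2 <- sentence("geen teken van koorts")
  expect_equal(find_triggers(s2, mini_lexicon(), "GP")$token_start, 0)
  expect_equal(nrow(find_triggers(sentence("alles rustig"),
                                  mini_lexicon(), "GP")), 0)

  gp_only <- mini_lexicon(trigger_entry("afwezig", "negation", "post",
                                        doc_types = "GP"))
  expect_true("afwezig" %in%
                find_triggers(sentence("koorts afwezig"), gp_only, "GP")$phrase)
  expect_false("afwezig" %in%
                 find_triggers(sentence("koorts afwezig"), gp_only, "RD")$phrase)
})

test_that("pseudo occurrences mask contained triggers", {
  occ <- find_triggers(sentence("niet minder krampen"), mini_lexicon(), "GP")
  expect_equal(occ$role, "pseudo")
  expect_equal(occ$phrase, "niet minder")
  # outside a pseudo span the same phrase still fires
  occ2 <- find_triggers(sentence("niet gespannen"), mini_lexicon(), "GP")
  expect_equal(occ2$phrase, "niet")
  expect_equal(occ2$role, "pre")
})

make_occ <- function(role, token_start, token_end, property = "negation") {
  data.frame(phrase = "x", property = property, role = role,
             token_start = as.integer(token_start),
             token_end = as.integer(token_end), char_start = 0L,
             char_end = 1L, max_scope_tokens = NA_integer_,
             stringsAsFactors = FALSE)
}

test_that("resolve_scope follows the documented defaults", {
  # sentence-end default: pre-trigger at token 0 of 8 covers [1, 8)
  s <- sentence(paste(letters[1:8], collapse = " "))
  sc <- resolve_scope(make_occ("pre", 0, 1), s, document_profile("RD"))
  expect_equal(sc, c(1, 8))

  # GP cap: 6 words from a 12-token sentence
  s12 <- sentence(paste(letters[1:12], collapse = " "))
  sc <- resolve_scope(make_occ("pre", 0, 1), s12, document_profile("GP"))
  expect_equal(sc, c(1, 7))
  # SP cap is 10
  sc <- resolve_scope(make_occ("pre", 0, 1), s12, document_profile("SP"))
  expect_equal(sc, c(1, 11))

  # punctuation terminator cuts the GP scope before the comma
  sg <- sentence("geen koorts , wel hoest")
  sc <- resolve_scope(make_occ("pre", 0, 1), sg, document_profile("GP"))
  expect_equal(sc, c(1, 2))
  # but not the RD scope (no punctuation terminators there)
  sc <- resolve_scope(make_occ("pre", 0, 1), sg, document_profile("RD"))
  expect_equal(sc, c(1, 5))

  # post-trigger mirrors leftwards
  sc <- resolve_scope(make_occ("post", 7, 8), s12, document_profile("GP"))
  expect_equal(sc, c(1, 7))
  sc <- resolve_scope(make_occ("post", 7, 8), s12, document_profile("RD"))
  expect_equal(sc, c(0, 7))

  # entry-level max_scope_tokens overrides the profile default
  occ <- make_occ("pre", 0, 1)
  occ$max_scope_tokens <- 2L
  expect_equal(resolve_scope(occ, s12, document_profile("RD")), c(1, 3))

  expect_error(resolve_scope(make_occ("pseudo", 0, 1), s12,
                             document_profile("GP")),
               "no scope for role pseudo")
})

test_that("lexicon termination triggers cut only their own property", {
  s <- sentence("geen a b maar c d")
  term <- make_occ("termination", 3, 4, property = "negation")
  sc <- resolve_scope(make_occ("pre", 0, 1), s, document_profile("RD"), term)
  expect_equal(sc, c(1, 3))
  sc2 <- resolve_scope(make_occ("pre", 0, 1, property = "historical"), s,
                       document_profile("RD"), term)
  expect_equal(sc2, c(1, 6))
})

# Independent scope oracle: candidate region, truncate at the first
# stopping token, then the first `cap` word tokens.  Compared on word
# (non-punctuation) membership -- punctuation cannot hold a mention.
oracle_scope_words <- function(role, ts, te, surfaces, stop_tok, cap) {
  n <- length(surfaces)
  punct <- surfaces %in% c(",", ";", ":", ".", "-", "<", ">")
  region <- if (role == "pre") {
    if (te <= n - 1) seq(te, n - 1) else integer()
  } else {
    if (ts >= 1) rev(seq(0, ts - 1)) else integer()
  }
  hit <- match(TRUE, stop_tok[region + 1])
  if (!is.na(hit)) region <- region[seq_len(hit - 1)]
  words <- region[!punct[region + 1]]
  sort(utils::head(words, cap))
}

scope_words <- function(sc, surfaces) {
  punct <- surfaces %in% c(",", ";", ":", ".", "-", "<", ">")
  idx <- if (sc[[1]] < sc[[2]]) seq(sc[[1]], sc[[2]] - 1) else integer()
  sort(idx[!punct[idx + 1]])
}

test_that("resolve_scope equals the brute-force oracle exhaustively", {
  profiles <- lapply(c("GP", "SP", "RD", "DL"), document_profile)
  for (n in c(1, 2, 3, 5, 8, 12)) {
    for (tp in seq_len(n) - 1L) {
      for (role in c("pre", "post")) {
        for (term_kind in c("none", "comma", "lexterm")) {
          qs <- if (term_kind == "none") NA else seq_len(n) - 1L
          for (q in qs) {
            if (!is.na(q) && q == tp) next
            surfaces <- paste0("w", seq_len(n))
            surfaces[tp + 1] <- "trig"
            terminators <- make_occ("termination", 0, 1)[0, ]
            if (term_kind == "comma") surfaces[q + 1] <- ","
            if (term_kind == "lexterm") {
              terminators <- make_occ("termination", q, q + 1)
            }
            s <- sentence(paste(surfaces, collapse = " "))
            for (pr in profiles) {
              occ <- make_occ(role, tp, tp + 1)
              got <- scope_words(resolve_scope(occ, s, pr, terminators),
                                 s$tokens$surface)
              stop_tok <- s$tokens$surface %in% pr$punctuation_terminators
              if (term_kind == "lexterm") stop_tok[q + 1] <- TRUE
              want <- oracle_scope_words(role, tp, tp + 1,
                                         s$tokens$surface, stop_tok,
                                         pr$default_scope_tokens)
              if (!identical(got, want)) {
                fail(sprintf("scope mismatch n=%d tp=%d role=%s term=%s q=%s profile=%s",
                             n, tp, role, term_kind, q, pr$doc_type))
              }
            }
          }
        }
      }
    }
  }
  succeed()
})

test_that("apply_context reproduces the documented behaviors", {
  lex <- default_lexicon()
  rules <- default_combined_rules()
  pats <- default_temporal_patterns()

  a <- annotate_one("Conclusie Geen oogheelkundige verklaring voor de hoofdpijn",
                    "hoofdpijn", "DL")
  expect_equal(a$negation, "Negated")  # known scope over-reach, by design

  a <- annotate_one("Hij heeft verder nooit medicijnen gebruikt die de tinnitus beinvloeden",
                    "tinnitus", "SP")
  expect_equal(a$negation, "NotNegated")  # bare 'nooit' is not a trigger

  a <- annotate_one("Moeder is recent gediagnosticeerd met kanker",
                    "kanker", "GP")
  expect_equal(a$experiencer, "Other")

  a <- annotate_one("met requip niet minder krampen en wel zwabberig",
                    "krampen", "GP")
  expect_equal(a$negation, "NotNegated")  # pseudo masking

  # no triggers: all defaults
  a <- annotate_one("vandaag controle wegens hoest", "hoest", "GP")
  expect_equal(c(a$negation, a$temporality, a$experiencer),
               c("NotNegated", "Recent", "Patient"))
  expect_equal(nrow(a$evidence[[1]]), 0)
})

test_that("GP minus rule negates trailing minus forms, gated by profile", {
  expect_equal(annotate_one("koorts-", "koorts", "GP")$negation, "Negated")
  expect_equal(annotate_one("koorts -", "koorts", "GP")$negation, "Negated")
  expect_equal(annotate_one("koorts- en hoest", "koorts", "GP")$negation,
               "Negated")
  expect_equal(annotate_one("koorts-", "koorts", "DL")$negation,
               "NotNegated")
  ev <- annotate_one("koorts-", "koorts", "GP")$evidence[[1]]
  expect_true("gp-minus" %in% ev$phrase_or_rule)

  # hyphen joining a following word is not a minus: pre-marked mention
  s <- sentence("koorts-achtig beeld")
  m <- manual_mention("koorts", 0, 6, 0, 1)
  a <- apply_context(s, m, default_lexicon(), NULL,
                     document_profile("GP"), NULL)
  expect_equal(a$negation, "NotNegated")
})

test_that("combined rules need both phrases within the span gate", {
  a <- annotate_one("Nooit urineweginfecties doorgemaakt",
                    "urineweginfecties", "GP")
  expect_equal(a$negation, "Negated")
  expect_setequal(a$evidence[[1]]$phrase_or_rule, c("nooit", "doorgemaakt"))

  a <- annotate_one("Nooit urineweginfecties", "urineweginfecties", "GP")
  expect_equal(a$negation, "NotNegated")

  far <- paste("nooit koorts", paste(rep("verder", 25), collapse = " "),
               "doorgemaakt")
  a <- annotate_one(far, "koorts", "RD")
  expect_equal(a$negation, "NotNegated")  # 25 tokens apart > span gate

  # profile gate
  s <- sentence("Nooit koorts doorgemaakt")
  m <- match_concepts(s, "koorts")
  off <- document_profile("GP", combined_rules_active = FALSE)
  expect_equal(apply_context(s, m, default_lexicon(), default_combined_rules(),
                             off, NULL)$negation, "NotNegated")
})

test_that("default preservation, overwrite order, self-overlap guard", {
  # empty lexicon, no rules: defaults everywhere
  s <- sentence("geen koorts maar wel hoest")
  m <- match_concepts(s, c("koorts", "hoest"))
  a <- apply_context(s, m, empty_lexicon(), NULL, document_profile("GP"),
                     NULL)
  expect_true(all(a$negation == "NotNegated" & a$temporality == "Recent" &
                    a$experiencer == "Patient"))

  # left-to-right overwrite: later trigger wins on the same property
  lex <- mini_lexicon(trigger_entry("zeker geen", "negation", "pre"))
  s2 <- sentence("geen idee maar zeker geen koorts")
  m2 <- match_concepts(s2, "koorts")
  a2 <- apply_context(s2, m2, lex, NULL, document_profile("RD"), NULL)
  expect_equal(a2$negation, "Negated")
  expect_equal(a2$evidence[[1]]$phrase_or_rule, "zeker geen")

  # a mention overlapping its trigger is not negated by it, even when
  # the mention extends into the trigger's scope
  s3 <- sentence("geen koorts vandaag")
  m3 <- manual_mention("geen koorts", 0, 11, 0, 2)
  a3 <- apply_context(s3, m3, mini_lexicon(), NULL, document_profile("GP"),
                      NULL)
  expect_equal(a3$negation, "NotNegated")

  expect_error(apply_context(s3, manual_mention("x", 0, 1, 0, 9),
                             mini_lexicon(), NULL, document_profile("GP"),
                             NULL),
               "outside sentence bounds")
})

test_that("annotations are deterministic and sentence-isolated", {
  lex <- default_lexicon()
  docs <- data.frame(
    id = c("a", "b"), doc_type = "GP",
    text = c("Geen koorts vandaag. Status na appendectomie.",
             "Geen koorts vandaag. Alles rustig verlopen."),
    stringsAsFactors = FALSE)
  terms <- c("koorts", "appendectomie")
  r1 <- annotate_documents(docs, terms, lex)
  r2 <- annotate_documents(docs, terms, lex)
  expect_identical(r1$annotations, r2$annotations)
  # first sentence annotation identical across different second sentences
  first_a <- r1$annotations[r1$annotations$doc_id == "a" &
                              r1$annotations$sentence_index == 0, ]
  first_b <- r1$annotations[r1$annotations$doc_id == "b" &
                              r1$annotations$sentence_index == 0, ]
  expect_equal(first_a[, c("term", "negation", "temporality", "experiencer")],
               first_b[, c("term", "negation", "temporality", "experiencer")],
               ignore_attr = TRUE)
})

test_that("terminator monotonicity: adding one never enlarges a scope", {
  set.seed(11)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    s <- sentence(paste(paste0("w", seq_len(n)), collapse = " "))
    role <- sample(c("pre", "post"), 1)
    tp <- sample(seq_len(n) - 1L, 1)
    occ <- make_occ(role, tp, tp + 1)
    pr <- document_profile(sample(c("GP", "SP", "RD", "DL"), 1))
    base <- resolve_scope(occ, s, pr)
    q <- sample(setdiff(seq_len(n) - 1L, tp), 1)
    withterm <- resolve_scope(occ, s, pr, make_occ("termination", q, q + 1))
    expect_true(withterm[[1]] >= base[[1]] && withterm[[2]] <= base[[2]])
  }
})
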