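# One-vs-rest metrics, Cohen's kappa, Altman bands.

test_that("score reproduces the hand-tallied 4-item fixture", {
  gold <- label_frame(c("Negated", "NotNegated", "Negated", "NotNegated"))
  pred <- label_frame(c("Negated", "NotNegated", "NotNegated", "Negated"))
  s <- score(gold, pred, "negation", "Negated")
  expect_equal(c(s$tp, s$fp, s$fn, s$tn), c(1, 1, 1, 1))
  expect_equal(c(s$precision, s$recall, s$f_score), c(0.5, 0.5, 0.5))

  perfect <- score(gold, gold, "negation", "Negated")
  expect_equal(c(perfect$precision, perfect$recall, perfect$f_score),
               c(1, 1, 1))
})

test_that("metrics are UNDEFINED (never 0-divided) and render as '-'", {
  gold <- label_frame(rep("NotNegated", 3))
  s <- score(gold, gold, "negation", "Negated")
  expect_true(is.na(s$precision) && is.na(s$recall) && is.na(s$f_score))
  expect_equal(format_metric(s$precision), "-")
  expect_equal(format_metric(0.926), "0.93")
})

test_that("score errors on unaligned mention sets, naming keys", {
  gold <- label_frame(c("Negated", "NotNegated"))
  pred <- label_frame(c("Negated", "NotNegated", "Negated"))
  expect_error(score(gold, pred, "negation", "Negated"),
               "missing keys: .*d03")
})

test_that("complementarity: swapping the positive class swaps counts", {
  set.seed(3)
  for (i in 1:20) {
    g <- label_frame(sample(c("Negated", "NotNegated"), 30, replace = TRUE))
    p <- label_frame(sample(c("Negated", "NotNegated"), 30, replace = TRUE))
    a <- score(g, p, "negation", "Negated")
    b <- score(g, p, "negation", "NotNegated")
    expect_equal(c(a$tp, a$fp, a$fn, a$tn), c(b$tn, b$fn, b$fp, b$tp))
    expect_equal(a$tp + a$fn, sum(g$negation == "Negated"))
    expect_equal(a$tp + a$fp, sum(p$negation == "Negated"))
  }
})

test_that("cohens_kappa matches the hand computation on the 2x2 fixture", {
  # table a=20 (X,X), b=5 (X,Y), c=10 (Y,X), d=15 (Y,Y); n=50
  a <- c(rep("X", 25), rep("Y", 25))
  b <- c(rep("X", 20), rep("Y", 5), rep("X", 10), rep("Y", 15))
  expect_equal(cohens_kappa(a, b), 0.4)
  expect_equal(agreement_band(cohens_kappa(a, b)), "fair")
})

test_that("kappa degenerate and error cases", {
  expect_equal(cohens_kappa(c("a", "b", "a"), c("a", "b", "a")), 1.0)
  expect_true(is.na(cohens_kappa(rep("a", 5), rep("a", 5))))
  expect_error(cohens_kappa(c("a", "b"), "a"), "differ in length")
})

# Independent oracle: count form of kappa from the contingency table,
#   (n * sum(diag) - sum(row * col)) / (n^2 - sum(row * col))
kappa_oracle <- function(a, b) {
  lv <- sort(unique(c(a, b)))
  tab <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(a)) tab[a[[i]], b[[i]]] <- tab[a[[i]], b[[i]]] + 1
  n <- length(a)
  srg <- sum(rowSums(tab) * colSums(tab))
  den <- n^2 - srg
  if (den == 0) return(NA_real_)
  (n * sum(diag(tab)) - srg) / den
}

test_that("kappa agrees with the count-form oracle on random pairings", {
  set.seed(101)
  alphabets <- list(c("x", "y"), c("x", "y", "z"), letters[1:5])
  for (i in 1:200) {
    lv <- alphabets[[sample(3, 1)]]
    n <- sample(2:60, 1)
    a <- sample(lv, n, replace = TRUE)
    b <- if (runif(1) < 0.3) a else sample(lv, n, replace = TRUE)
    k1 <- cohens_kappa(a, b)
    k2 <- kappa_oracle(a, b)
    if (is.na(k1) || is.na(k2)) {
      expect_identical(is.na(k1), is.na(k2))
    } else {
      expect_equal(k1, k2, tolerance = 1e-12)
    }
  }
})

test_that("kappa is invariant under label permutation", {
  set.seed(5)
  a <- sample(c("Recent", "Historical", "Hypothetical"), 60, replace = TRUE)
  b <- sample(c("Recent", "Historical", "Hypothetical"), 60, replace = TRUE)
  relabel <- c(Recent = "r2", Historical = "h9", Hypothetical = "q1")
  expect_equal(cohens_kappa(a, b),
               cohens_kappa(unname(relabel[a]), unname(relabel[b])))
})

test_that("agreement bands follow the Altman cut points", {
  expect_equal(agreement_band(0.90), "very good")
  expect_equal(agreement_band(0.46), "moderate")
  expect_equal(agreement_band(0.61), "good")
  expect_equal(agreement_band(0.20), "poor")
  expect_equal(agreement_band(0.21), "fair")
  expect_equal(agreement_band(0.80), "good")
  expect_equal(agreement_band(0.81), "very good")
  expect_equal(agreement_band(-0.3), "poor")
  expect_error(agreement_band(1.2), "must lie")
})

test_that("evaluate_annotations reports per doc type plus micro ALL", {
  gold <- rbind(label_frame(c("Negated", "NotNegated"), doc_type = "GP"),
                label_frame(c("Negated", "Negated"), doc_type = "RD"))
  gold$doc_id <- sprintf("d%02d", 1:4)
  pred <- gold
  pred$negation <- c("Negated", "Negated", "Negated", "NotNegated")
  rep <- evaluate_annotations(gold, pred)
  expect_s3_class(rep, "evaluation_report")
  expect_setequal(unique(rep$doc_type), c("ALL", "GP", "RD"))
  neg_all <- rep[rep$doc_type == "ALL" & rep$value == "Negated", ]
  expect_equal(neg_all$tp, 2)
  expect_equal(neg_all$fp, 1)
  expect_equal(neg_all$fn, 1)
  gp <- rep[rep$doc_type == "GP" & rep$value == "Negated", ]
  expect_equal(gp$precision, 0.5)
  expect_equal(gp$recall, 1)
})
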