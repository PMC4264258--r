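# Evaluation: one-vs-rest precision/recall/F per property value, and
# Cohen's kappa for inter-annotator agreement.
#
# Metrics with a zero denominator are UNDEFINED (NA), never 0, and are
# rendered as "-" in formatted reports.

PROPERTY_VALUES <- list(
  negation = c("Negated", "NotNegated"),
  temporality = c("Recent", "Historical", "Hypothetical"),
  experiencer = c("Patient", "Other"))

mention_key <- function(ann) {
  paste(ann$doc_id, ann$sentence_index, ann$char_start, ann$char_end,
        sep = "|")
}

safe_div <- function(num, den) if (den > 0) num / den else NA_real_

#' One-vs-rest confusion counts and metrics for one property value
#'
#' Gold and predicted annotations are aligned on the mention key
#' (doc_id, sentence_index, character span); the chosen value is the
#' positive class, all other values of the property combined form the
#' negative class.
#'
#' @param gold,pred Annotation data frames (same mention sets).
#' @param property `"negation"`, `"temporality"` or `"experiencer"`.
#' @param positive_value The property value taken as positive class.
#' @return List of class `confusion_counts` with `tp`, `fp`, `fn`,
#'   `tn`, `precision`, `recall`, `f_score` (metrics `NA` when their
#'   denominator is zero).
#' @export
score <- function(gold, pred, property, positive_value) {
  stopifnot(property %in% names(PROPERTY_VALUES))
  gk <- mention_key(gold)
  pk <- mention_key(pred)
  missing_in_pred <- setdiff(gk, pk)
  missing_in_gold <- setdiff(pk, gk)
  if (length(missing_in_pred) || length(missing_in_gold)) {
    stop("gold/pred mention sets differ; missing keys: ",
         paste(utils::head(c(missing_in_pred, missing_in_gold), 5),
               collapse = ", "))
  }
  g <- gold[[property]][match(pk, gk)]
  p <- pred[[property]]
  gp <- g == positive_value
  pp <- p == positive_value
  tp <- sum(gp & pp); fp <- sum(!gp & pp)
  fn <- sum(gp & !pp); tn <- sum(!gp & !pp)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f_score <- if (is.na(precision) || is.na(recall)) NA_real_
             else if (precision + recall == 0) NA_real_
             else 2 * precision * recall / (precision + recall)
  structure(list(positive_class = positive_value, tp = tp, fp = fp,
                 fn = fn, tn = tn, precision = precision, recall = recall,
                 f_score = f_score),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> positive:", x$positive_class,
      sprintf("tp=%d fp=%d fn=%d tn=%d  P=%s R=%s F=%s", x$tp, x$fp,
              x$fn, x$tn, format_metric(x$precision),
              format_metric(x$recall), format_metric(x$f_score)), "\n")
  invisible(x)
}

#' Render a metric, mapping UNDEFINED to "-"
#' @param x Numeric metric or `NA`.
#' @param digits Rounding digits.
#' @return Character scalar.
#' @export
format_metric <- function(x, digits = 2) {
  if (is.na(x)) "-" else formatC(round(x, digits), format = "f",
                                 digits = digits)
}

#' Full evaluation report over all properties and values
#'
#' One row per (property, value) and, when `by_doc_type`, per document
#' type, mirroring the per-document-type layout customary for this
#' evaluation; a micro-averaged "ALL" block is always included.
#'
#' @param gold,pred Aligned annotation data frames; a `doc_type` column
#'   is required for the per-type breakdown.
#' @param by_doc_type Split the report by document type.
#' @return Data frame of class `evaluation_report`.
#' @export
evaluate_annotations <- function(gold, pred, by_doc_type = TRUE) {
  groups <- list(ALL = rep(TRUE, nrow(gold)))
  if (by_doc_type && "doc_type" %in% names(gold)) {
    for (dt in intersect(DOC_TYPES, unique(gold$doc_type))) {
      groups[[dt]] <- gold$doc_type == dt
    }
  }
  gk <- mention_key(gold)
  pk <- mention_key(pred)
  pred <- pred[match(gk, pk), , drop = FALSE]
  rows <- list()
  for (gname in names(groups)) {
    sel <- groups[[gname]]
    for (property in names(PROPERTY_VALUES)) {
      for (v in PROPERTY_VALUES[[property]]) {
        s <- score(gold[sel, , drop = FALSE], pred[sel, , drop = FALSE],
                   property, v)
        rows[[length(rows) + 1L]] <- data.frame(
          doc_type = gname, property = property, value = v,
          n_gold = s$tp + s$fn, tp = s$tp, fp = s$fp, fn = s$fn,
          tn = s$tn, precision = s$precision, recall = s$recall,
          f_score = s$f_score, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  y <- as.data.frame(x)
  for (col in c("precision", "recall", "f_score")) {
    y[[col]] <- vapply(y[[col]], format_metric, character(1))
  }
  print(y)
  invisible(x)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' marginal-product chance agreement.  When the expected agreement is 1
#' (both annotators constant on the same label) kappa is undefined and
#' `NA` is returned.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Kappa in `[-1, 1]`, or `NA` when undefined.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors differ in length: ", length(labels_a), " vs ",
         length(labels_b))
  }
  if (length(labels_a) == 0) stop("need at least one label pair")
  lv <- sort(unique(c(labels_a, labels_b)))
  a <- factor(labels_a, levels = lv)
  b <- factor(labels_b, levels = lv)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Qualitative agreement band for a kappa value
#'
#' Conventional interpretation bands: up to 0.20 poor, 0.21-0.40 fair,
#' 0.41-0.60 moderate, 0.61-0.80 good, 0.81-1.00 very good.
#'
#' @param kappa Numeric in `[-1, 1]`.
#' @return One of `"poor"`, `"fair"`, `"moderate"`, `"good"`,
#'   `"very good"`.
#' @export
agreement_band <- function(kappa) {
  if (is.na(kappa) || kappa < -1 || kappa > 1) {
    stop("kappa must lie in [-1, 1]")
  }
  if (kappa <= 0.20) "poor"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "good"
  else "very good"
}
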