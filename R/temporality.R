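# Temporality module: regular-expression detection of Historical
# evidence in adjusted token windows around a concept mention.
#
# The trigger lexicon carries few historical phrases; most historical
# statements in Dutch clinical text are duration expressions ("2 jaar
# geleden", "sinds 3 maanden") best caught by regexes.  A condition is
# Recent when at most 2 weeks old, so shipped duration patterns only
# fire beyond the 14-day bound -- the thresholds are encoded in the
# regexes themselves so a pattern file stays fully declarative.

#' Construct a temporal pattern
#'
#' @param id Unique pattern identifier.
#' @param regex Case-insensitive Perl regex applied to the window text.
#' @param side `"left"`, `"right"` or `"either"`: which side of the
#'   mention the window lies on.
#' @param window_tokens Window width in tokens from the mention edge.
#' @param guard Optional regex; a guard match in the same window vetoes
#'   the pattern (e.g. a relational operator next to the number, or
#'   "net"/"recent" marking the event as fresh).
#' @param requires_reference Logical; when `TRUE` the first capture
#'   group is a 4-digit year that must be strictly before the document
#'   reference year (pattern is skipped if no reference year is known).
#' @return One-row data frame with the pattern schema.
#' @export
temporal_pattern <- function(id, regex, side = c("either", "left", "right"),
                             window_tokens = 5L, guard = NA_character_,
                             requires_reference = FALSE) {
  side <- match.arg(side)
  window_tokens <- as.integer(window_tokens)
  if (window_tokens < 1L) stop("window_tokens must be >= 1")
  tryCatch(suppressWarnings(grepl(regex, "", perl = TRUE)),
           error = function(e) stop("invalid regex for pattern '", id, "': ",
                                    conditionMessage(e), call. = FALSE))
  if (!is.na(guard)) {
    tryCatch(suppressWarnings(grepl(guard, "", perl = TRUE)),
             error = function(e) stop("invalid guard for pattern '", id,
                                      "'", call. = FALSE))
  }
  data.frame(id = id, regex = regex, side = side,
             window_tokens = window_tokens, guard = guard,
             requires_reference = isTRUE(requires_reference),
             stringsAsFactors = FALSE)
}

#' Load temporal patterns from a YAML file
#'
#' The file is a YAML list of mappings with keys `id`, `regex`, `side`,
#' `window_tokens` and optional `guard`, `requires_reference`.
#'
#' @param path Path to the YAML file.
#' @return Data frame of compiled patterns.
#' @export
load_temporal_patterns <- function(path) {
  if (!file.exists(path)) stop("patterns file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0) return(temporal_pattern("x", "x")[0, ])
  pats <- do.call(rbind, lapply(raw, function(p) {
    if (is.null(p$id) || is.null(p$regex)) {
      stop("pattern entries need at least 'id' and 'regex'")
    }
    temporal_pattern(p$id, p$regex,
                     side = if (is.null(p$side)) "either" else p$side,
                     window_tokens = if (is.null(p$window_tokens)) 5L
                                     else p$window_tokens,
                     guard = if (is.null(p$guard)) NA_character_ else p$guard,
                     requires_reference = isTRUE(p$requires_reference))
  }))
  if (anyDuplicated(pats$id)) {
    stop("duplicate pattern id '", pats$id[duplicated(pats$id)][[1]], "'")
  }
  pats
}

#' The bundled temporal pattern set
#'
#' Loaded from the package's `extdata/temporal_patterns.yaml`.
#' @return Data frame of patterns.
#' @export
default_temporal_patterns <- function() {
  path <- system.file("extdata", "temporal_patterns.yaml",
                      package = "contextnl")
  if (!nzchar(path)) stop("bundled temporal_patterns.yaml not found")
  load_temporal_patterns(path)
}

window_span <- function(sent, mention, side, w) {
  toks <- sent$tokens
  n <- nrow(toks)
  if (side == "left") {
    lo <- max(0L, mention$token_start - w)
    hi <- mention$token_start
  } else {
    lo <- mention$token_end
    hi <- min(n, mention$token_end + w)
  }
  if (lo >= hi) return(NULL)
  substring(sent$text, toks$start[[lo + 1L]] + 1L, toks$end[[hi]])
}

#' Detect Historical evidence around a mention
#'
#' A pattern fires when its regex matches inside its token window on its
#' side of the mention and its guard does not match in the same window.
#' Windows never cross the sentence boundary.
#'
#' @param sent A `clinical_sentence`.
#' @param mention One mention row from [match_concepts()].
#' @param patterns Pattern data frame, e.g.
#'   [default_temporal_patterns()].
#' @param reference_year Optional document reference year; patterns with
#'   `requires_reference` are skipped when it is `NA`.
#' @return List with `historical` (logical) and `pattern_ids`
#'   (character vector of patterns that fired).
#' @export
detect_historical <- function(sent, mention,
                              patterns = default_temporal_patterns(),
                              reference_year = NA_integer_) {
  stopifnot(inherits(sent, "clinical_sentence"))
  fired <- character()
  for (i in seq_len(nrow(patterns))) {
    p <- patterns[i, ]
    if (p$requires_reference && is.na(reference_year)) next
    sides <- if (p$side == "either") c("left", "right") else p$side
    for (s in sides) {
      win <- window_span(sent, mention, s, p$window_tokens)
      if (is.null(win)) next
      m <- regexpr(p$regex, win, ignore.case = TRUE, perl = TRUE)
      if (m == -1) next
      if (!is.na(p$guard) &&
          grepl(p$guard, win, ignore.case = TRUE, perl = TRUE)) next
      if (p$requires_reference) {
        hit <- regmatches(win, m)
        yr <- suppressWarnings(as.integer(
          sub(".*?((?:19|20)[0-9]{2}).*", "\\1", hit)))
        if (is.na(yr) || yr >= reference_year) next
      }
      fired <- c(fired, p$id)
      break
    }
  }
  list(historical = length(fired) > 0, pattern_ids = unique(fired))
}
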